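#' Run the full field-based QSAR pipeline
#'
#' One call from aligned (or alignable) molecules plus activities to a
#' fitted, validated model: optional skeleton alignment onto the most
#' active compound, grid construction, field evaluation (CoMFA probe
#' energies or CoMSIA similarity indices), descriptor filtering/scaling
#' referenced to the training set, leave-one-out component selection, the
#' final PLS fit with its non-cross-validated statistics and field
#' contributions, and - when test compounds are present - external
#' prediction with the through-origin validation battery.
#'
#' @param molecules list of [molecule()] objects.
#' @param records activity data.frame (`id`, `pic50`, `role`), same
#'   compounds as `molecules`.
#' @param model `"comfa"` or `"comsia"`.
#' @param kinds CoMSIA property kinds (ignored for CoMFA).
#' @param probe a `qsar_probe`.
#' @param spacing,margin grid geometry (Angstrom) when `grid` is NULL.
#' @param grid optional pre-built `qsar_grid`.
#' @param filter_sigma minimum-sigma column filter; default 2.0 for CoMFA
#'   energies, 0.05 for the smaller-magnitude CoMSIA similarity indices.
#' @param scaling passed to [build_block()].
#' @param max_components,parsimony_tol passed to [loo_q2()].
#' @param align superpose skeletons onto `template_id` first?
#' @param template_id alignment template (default: most active compound).
#' @return list of class `qsar_fit`: `model` (`pls_model`), `block`,
#'   `cv` (`crossval_report`), `stats` (r2/SEE/F), `contributions`,
#'   `external` (list with `predicted`, `rpred2`, `battery`, `tropsha`;
#'   NULL without test compounds), `records`, `train_idx`, `test_idx`.
#' @export
qsar_pipeline <- function(molecules, records,
                          model = c("comsia", "comfa"),
                          kinds = c("steric", "hydrophobic", "donor",
                                    "acceptor"),
                          probe = default_probe(),
                          spacing = 2.0, margin = 4.0, grid = NULL,
                          filter_sigma = NULL,
                          scaling = "comfa_std",
                          max_components = 10L, parsimony_tol = 0.05,
                          align = FALSE, template_id = NULL) {
  model <- match.arg(model)
  ids <- vapply(molecules, `[[`, character(1), "id")
  if (!setequal(ids, records$id)) {
    stop("molecule ids and activity record ids differ")
  }
  records <- records[match(ids, records$id), ]
  if (align) {
    if (is.null(template_id)) {
      template_id <- records$id[which.max(records$pic50)]
    }
    molecules <- align_set(molecules, template_id)
  }
  if (is.null(grid)) grid <- make_grid(molecules, spacing, margin)
  if (is.null(filter_sigma)) {
    filter_sigma <- if (model == "comfa") 2.0 else 0.05
  }
  train_idx <- which(records$role == "training")
  test_idx <- which(records$role == "test")
  if (length(train_idx) < 4L) stop("need at least 4 training compounds")
  fieldset <- compute_fields(molecules, grid, probe, model = model,
                             kinds = kinds)
  block <- build_block(fieldset, filter_sigma = filter_sigma,
                       scaling = scaling, ref_rows = train_idx)
  X_train <- block$matrix[train_idx, , drop = FALSE]
  y_train <- records$pic50[train_idx]
  cv <- loo_q2(X_train, y_train, max_components = max_components,
               parsimony_tol = parsimony_tol)
  fit <- fit_pls(X_train, y_train, cv$onc)
  stats <- fit_statistics(fit, X_train, y_train)
  contributions <- field_contributions(fit, block, rows = train_idx)
  external <- NULL
  if (length(test_idx) >= 3L) {
    y_test <- records$pic50[test_idx]
    y_pred <- predict(fit, block$matrix[test_idx, , drop = FALSE])
    battery <- external_battery(y_test, y_pred)
    external <- list(
      predicted = data.frame(id = records$id[test_idx],
                             experimental = y_test, predicted = y_pred),
      rpred2 = rpred2(y_test, y_pred, mean(y_train)),
      battery = battery,
      tropsha = tropsha_conditions(battery)
    )
  }
  structure(list(model = fit, block = block, cv = cv, stats = stats,
                 contributions = contributions, external = external,
                 records = records, train_idx = train_idx,
                 test_idx = test_idx),
            class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat(sprintf("<qsar_fit: ONC %d, q2 %.3f, r2 %.3f, SEE %.3f, F %.1f>\n",
              x$cv$onc, x$cv$q2_onc, x$stats$r2, x$stats$see,
              x$stats$f_value))
  cat("  contributions:",
      paste(sprintf("%s %.3f", names(x$contributions), x$contributions),
            collapse = ", "), "\n")
  if (!is.null(x$external)) {
    cat(sprintf("  external: Rpred2 %.3f, rm2 %.3f, Tropsha overall %s\n",
                x$external$rpred2, x$external$battery$rm2,
                if (x$external$tropsha$overall) "pass" else "FAIL"))
  }
  invisible(x)
}
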