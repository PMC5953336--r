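#' Export a fit-statistics grid as CSV
#'
#' Writes the per-occasion, per-class-count statistic grid (as built at
#' Step 0) in the conventional layout: one row per fitted model with
#' columns `G2`, `AIC`, `BIC`, `CAIC`, `ABIC`, `Entropy`, `DF`.
#'
#' @param grid a `candidate_pool`, or its `grid` data frame.
#' @param file output CSV path.
#' @return Invisibly, the path written.
#' @export
write_fit_grid <- function(grid, file) {
  if (inherits(grid, "candidate_pool")) grid <- grid$grid
  out <- data.frame(Occasion = grid$occasion, Classes = grid$S,
                    G2 = grid$G2, AIC = grid$AIC, BIC = grid$BIC,
                    CAIC = grid$CAIC, ABIC = grid$ABIC,
                    Entropy = grid$entropy, DF = grid$df)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Export a fitted model as CSV blocks, a JSON manifest and a text log
#'
#' Writes, under `dir` with the given `stem`:
#' `<stem>_rho.csv` (rows = status x item x occasion set, columns =
#' response categories), `<stem>_prevalence.csv` (status prevalences --
#' the model-implied chain marginals per occasion for a transition
#' model), `<stem>_transitions.csv` (stacked transition matrices, one
#' block per adjacent occasion pair), `<stem>_coefficients.csv`
#' (prevalence logit intercepts, covariate coefficients and their odds,
#' reference status marked; only when covariates are present),
#' `<stem>_manifest.json` (spec, log-likelihood, fit statistics,
#' convergence), and `<stem>_convergence.txt`.
#'
#' @param fit an `lca_fit` or `lta_fit`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"fit"`).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_fit <- function(fit, dir, stem = "fit") {
  stopifnot(inherits(fit, c("lca_fit", "lta_fit")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  path <- function(suffix) file.path(dir, paste0(stem, "_", suffix))

  rho_rows <- function(rho, set_name) {
    S <- dim(rho)[1L]; J <- dim(rho)[2L]; C <- dim(rho)[3L]
    items <- dimnames(rho)[[2L]]
    if (is.null(items)) items <- paste0("item", seq_len(J))
    do.call(rbind, lapply(seq_len(S), function(s)
      data.frame(set = set_name, status = s, item = items,
                 matrix(rho[s, , ], J, C,
                        dimnames = list(NULL, paste0("cat", seq_len(C)))))))
  }
  rho <- fit$rho
  rho_df <- if (is.list(rho))
    do.call(rbind, lapply(seq_along(rho), function(t)
      rho_rows(rho[[t]], paste0("occasion", t))))
  else rho_rows(rho, "all-occasions")
  utils::write.csv(rho_df, path("rho.csv"), row.names = FALSE)
  paths["rho"] <- path("rho.csv")

  prev <- if (inherits(fit, "lta_fit")) {
    data.frame(occasion = seq_len(nrow(fit$occupancy)), fit$occupancy)
  } else {
    data.frame(occasion = 1L,
               matrix(fit$gamma, 1L,
                      dimnames = list(NULL,
                                      paste0("class", seq_along(fit$gamma)))))
  }
  utils::write.csv(prev, path("prevalence.csv"), row.names = FALSE)
  paths["prevalence"] <- path("prevalence.csv")

  if (inherits(fit, "lta_fit") && length(fit$tau)) {
    tau_df <- do.call(rbind, lapply(seq_along(fit$tau), function(t) {
      tm <- fit$tau[[t]]
      if (is.list(tm)) tm <- tm[[1L]]
      data.frame(transition = paste0("t", t, "->t", t + 1L),
                 origin = seq_len(nrow(tm)),
                 matrix(tm, nrow(tm),
                        dimnames = list(NULL,
                                        paste0("to_status",
                                               seq_len(ncol(tm))))))
    }))
    utils::write.csv(tau_df, path("transitions.csv"), row.names = FALSE)
    paths["transitions"] <- path("transitions.csv")
  }

  if (!is.null(fit$beta)) {
    b <- fit$beta
    coef_df <- rbind(
      data.frame(quantity = paste0("beta_", colnames(b)),
                 reference = 0, t(b), check.names = FALSE),
      data.frame(quantity = paste0("odds_", colnames(b)),
                 reference = 1, t(exp(b)), check.names = FALSE))
    utils::write.csv(coef_df, path("coefficients.csv"), row.names = FALSE)
    paths["coefficients"] <- path("coefficients.csv")
  }

  manifest <- list(
    model = if (inherits(fit, "lta_fit")) "lta" else "lca",
    S = fit$S, loglik = fit$loglik, stats = fit$stats,
    convergence = fit$convergence)
  if (inherits(fit, "lta_fit"))
    manifest$spec <- unclass(fit$spec)[c(
      "S", "measurement_invariance", "transition_invariance",
      "covariates", "covariate_on_transitions", "starts", "seed", "tol",
      "max_iter")]
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  paths["manifest"] <- path("manifest.json")

  cv <- fit$convergence
  log_lines <- c(
    sprintf("random starts: %d", cv$n_starts),
    sprintf("best log-likelihood: %.8f", cv$best_loglik),
    sprintf("starts reaching best: %d", cv$n_starts_at_best),
    sprintf("best run converged: %s", cv$converged),
    sprintf("iterations per start: %s",
            paste(cv$iterations, collapse = ", ")))
  writeLines(log_lines, path("convergence.txt"))
  paths["convergence"] <- path("convergence.txt")
  invisible(paths)
}
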