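#' Framework settings
#'
#' Bundles the knobs of the staged model-building workflow so one config
#' object (embeddable in reports) controls every step: candidate class
#' range, significance level, criterion set, arbiter between the
#' difference test and the criteria, start counts and the master seed.
#'
#' @param class_range candidate class counts scanned at Step 0.
#' @param alpha significance level for the likelihood-ratio difference
#'   tests.
#' @param criteria information criteria admitted when building the
#'   candidate pool.
#' @param selection_criterion criterion used to pick among surviving
#'   candidates (AIC by default; a BIC disagreement is always flagged).
#' @param arbiter decides when LRDT and criteria conflict in invariance
#'   tests: `"lrdt"` (default), `"aic"` or `"bic"`.
#' @param starts_lca,starts_lta random starts for cross-sectional and
#'   longitudinal fits.
#' @param seed master seed; each step derives its own stream from it.
#' @param tol,max_iter EM settings.
#' @param highlight_threshold item-response probability above which a
#'   profile entry is highlighted when defining statuses.
#' @param include,exclude manual candidate-pool overrides (class counts),
#'   recorded in the report.
#' @param covariates covariate column names for Step 4 (empty = skip).
#' @param covariate_on_transitions also try transition covariates at
#'   Step 4 (sparseness failures are reported as findings).
#' @param labels optional status labels attached at Step 2.
#' @return A `framework_config` list.
#' @export
framework_config <- function(class_range = 1:6, alpha = 0.05,
                             criteria = c("AIC", "BIC", "CAIC", "ABIC"),
                             selection_criterion = "AIC",
                             arbiter = "lrdt",
                             starts_lca = 20L, starts_lta = 10L,
                             seed = 1L, tol = 1e-8, max_iter = 2000L,
                             highlight_threshold = 0.5,
                             include = NULL, exclude = NULL,
                             covariates = NULL,
                             covariate_on_transitions = FALSE,
                             labels = NULL) {
  criteria <- match.arg(criteria, c("AIC", "BIC", "CAIC", "ABIC"),
                        several.ok = TRUE)
  structure(as.list(environment()), class = "framework_config")
}

#' Step 0: cross-sectional candidate pool
#'
#' Fits an LCA at every occasion for every class count in the range and
#' assembles the fit-statistic grid (G2, AIC, BIC, CAIC, ABIC, entropy,
#' df).  A class count enters the pool when it minimizes at least one
#' admitted criterion at at least one occasion; entropy is reported for
#' context but never drives pool membership (classification certainty is
#' not a fit measure).  Manual `include`/`exclude` overrides are honored
#' and logged -- substantive screening of a criterion-favored solution is
#' a legitimate, but always explicit, decision.
#'
#' @param panel a [response_panel()].
#' @param class_range candidate class counts.
#' @param config a [framework_config()] (its `class_range` is overridden
#'   by the argument).
#' @return A `candidate_pool`: `grid` (data frame), `pool` (class
#'   counts), `support` (which criterion favored which count where),
#'   `overrides`.
#' @export
step0_candidate_pool <- function(panel, class_range = NULL,
                                 config = framework_config()) {
  if (is.null(class_range)) class_range <- config$class_range
  t_occ <- n_occasions(panel)
  rows <- list(); fits <- list()
  for (tt in seq_len(t_occ)) {
    pt <- pattern_frequencies(panel, "occasion", tt)
    if (max(class_range) > nrow(pt$patterns))
      stop("class range exceeds the number of distinct patterns at occasion ",
           tt)
    for (s in class_range) {
      fit <- suppressWarnings(fit_lca(
        pt, s, starts = config$starts_lca,
        seed = config$seed + 1000L * tt + s,
        tol = config$tol, max_iter = config$max_iter))
      fits[[sprintf("t%d_S%d", tt, s)]] <- fit
      st <- fit$stats
      rows[[length(rows) + 1L]] <- data.frame(
        occasion = tt, S = s, loglik = st$loglik, G2 = st$G2,
        AIC = st$AIC, BIC = st$BIC, CAIC = st$CAIC, ABIC = st$ABIC,
        entropy = st$entropy, df = st$df, P = st$P)
    }
  }
  grid <- do.call(rbind, rows)
  support <- list()
  for (tt in seq_len(t_occ)) for (cr in config$criteria) {
    sub <- grid[grid$occasion == tt, ]
    best <- sub$S[which.min(sub[[cr]])]
    support[[length(support) + 1L]] <- data.frame(
      occasion = tt, criterion = cr, S = best)
  }
  support <- do.call(rbind, support)
  pool <- sort(unique(support$S))
  overrides <- list(include = config$include, exclude = config$exclude)
  pool <- sort(union(pool, config$include))
  pool <- setdiff(pool, config$exclude)
  if (length(pool) == 0L)
    stop("candidate pool is empty; widen the class range or drop the exclusions")
  structure(list(grid = grid, pool = pool, support = support,
                 overrides = overrides, fits = fits),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("Candidate pool:", paste(x$pool, collapse = ", "), "\n")
  for (cr in unique(x$support$criterion)) {
    sub <- x$support[x$support$criterion == cr, ]
    cat(sprintf("  %s favors: %s (by occasion)\n", cr,
                paste(sub$S, collapse = ", ")))
  }
  invisible(x)
}

#' Step 1: longitudinal measurement invariance
#'
#' For each candidate class count, fits the latent transition model twice
#' -- item-response probabilities free per occasion versus held invariant
#' -- and runs the likelihood-ratio difference test.  Invariance retained
#' means the statuses keep one meaning over time and the candidate
#' survives; if no candidate survives, the recommended fallback is
#' repeated-measures LCA with occasion-specific classes (reported as an
#' outcome, not an error).
#'
#' @param panel a [response_panel()].
#' @param pool a `candidate_pool` or an integer vector of class counts.
#' @param config a [framework_config()].
#' @return A `step1_result`: per-candidate list (invariant fit, free fit,
#'   comparison, survives) plus `surviving` and possibly `fallback`.
#' @export
step1_measurement_invariance <- function(panel, pool,
                                         config = framework_config()) {
  if (inherits(pool, "candidate_pool")) pool <- pool$pool
  stopifnot(length(pool) >= 1L)
  results <- list()
  for (s in pool) {
    res <- tryCatch({
      fit_inv <- suppressWarnings(fit_lta(panel, lta_spec(
        s, measurement_invariance = TRUE, starts = config$starts_lta,
        seed = config$seed + 20000L + s, tol = config$tol,
        max_iter = config$max_iter)))
      fit_free <- suppressWarnings(fit_lta(panel, lta_spec(
        s, measurement_invariance = FALSE, starts = config$starts_lta,
        seed = config$seed + 30000L + s, tol = config$tol,
        max_iter = config$max_iter)))
      cmp <- lrdt(fit_inv, fit_free, alpha = config$alpha,
                  arbiter = config$arbiter)
      list(S = s, fit_invariant = fit_inv, fit_free = fit_free,
           comparison = cmp,
           survives = cmp$decision == "restricted_retained")
    }, lta_estimation_error = function(e)
      list(S = s, error = conditionMessage(e), survives = FALSE))
    results[[as.character(s)]] <- res
  }
  surviving <- pool[vapply(results, `[[`, logical(1L), "survives")]
  out <- list(results = results, surviving = surviving)
  if (length(surviving) == 0L)
    out$fallback <- paste(
      "no candidate holds longitudinal measurement invariance;",
      "consider repeated-measures LCA with occasion-specific classes")
  structure(out, class = "step1_result")
}

#' Step 2: define latent statuses
#'
#' Selects among the surviving candidates by the configured criterion
#' (with a mandatory conflict warning when AIC and BIC disagree) and lays
#' out the status profile: the item-response probability of each item's
#' top category per status, entries at or above the highlight threshold
#' marked, statuses ordered by descending first-occasion prevalence.  A
#' status whose every item is highlighted is flagged globally elevated.
#' Substantive labels are user input, never derived automatically.
#'
#' @param x an `lta_fit` (single candidate) or a `step1_result`.
#' @param threshold highlight threshold on the profile entries.
#' @param labels optional character labels, one per status.
#' @param criterion selection criterion among surviving candidates.
#' @return A `status_profile`: `fit`, `profile` (items x statuses),
#'   `highlighted`, `globally_elevated`, `prevalence`, `labels`,
#'   `selection` (criterion bookkeeping incl. conflict flag).
#' @export
step2_define_statuses <- function(x, threshold = 0.5, labels = NULL,
                                  criterion = "AIC") {
  selection <- NULL
  if (inherits(x, "step1_result")) {
    surv <- x$surviving
    if (length(surv) == 0L)
      stop("no surviving candidates to define statuses from")
    fits <- lapply(as.character(surv),
                   function(s) x$results[[s]]$fit_invariant)
    vals <- vapply(fits, function(f) f$stats[[criterion]], numeric(1L))
    pick <- which.min(vals)
    bic_vals <- vapply(fits, function(f) f$stats$BIC, numeric(1L))
    conflict <- surv[which.min(bic_vals)] != surv[pick]
    if (conflict)
      warning(sprintf(
        "criterion conflict: %s selects S = %d but BIC selects S = %d; selection follows %s",
        criterion, surv[pick], surv[which.min(bic_vals)], criterion))
    fit <- fits[[pick]]
    selection <- list(criterion = criterion, candidates = surv,
                      values = stats::setNames(vals, surv),
                      BIC = stats::setNames(bic_vals, surv),
                      selected = surv[pick], conflict = conflict)
  } else fit <- x
  rho <- if (is.list(fit$rho)) fit$rho[[1L]] else fit$rho
  S <- dim(rho)[1L]; items <- dimnames(rho)[[2L]]
  cj <- fit$prep$cj
  profile <- t(vapply(seq_len(S), function(s)
    vapply(seq_along(items), function(j) rho[s, j, cj[j]], numeric(1L)),
    numeric(length(items))))
  dimnames(profile) <- list(paste0("status", seq_len(S)), items)
  profile <- t(profile)  # items x statuses, the familiar profile layout
  highlighted <- profile >= threshold
  globally_elevated <- apply(highlighted, 2L, all)
  if (!is.null(labels)) {
    if (length(labels) != S) stop("need one label per status")
    colnames(profile) <- colnames(highlighted) <- labels
    names(globally_elevated) <- labels
  }
  structure(
    list(fit = fit, profile = profile, highlighted = highlighted,
         globally_elevated = globally_elevated,
         prevalence = fit$occupancy[1L, ], threshold = threshold,
         labels = labels, selection = selection),
    class = "status_profile")
}

#' @export
print.status_profile <- function(x, ...) {
  cat("Status profile (top-category response probabilities;",
      sprintf("* marks entries >= %.2f):\n", x$threshold))
  disp <- matrix(sprintf("%.4f%s", x$profile,
                         ifelse(x$highlighted, "*", " ")),
                 nrow(x$profile),
                 dimnames = dimnames(x$profile))
  print(disp, quote = FALSE)
  if (any(x$globally_elevated))
    cat("globally elevated:",
        paste(colnames(x$profile)[x$globally_elevated], collapse = ", "),
        "\n")
  invisible(x)
}

#' Step 3: transition-probability (and group) invariance
#'
#' With three or more occasions, compares the model whose transition
#' matrix is shared across all adjacent occasion pairs against the free
#' model; with two occasions there is a single transition matrix and the
#' test is skipped with a note.  When the panel is grouped and the config
#' asks for it, prevalence and transition homogeneity across groups are
#' tested the same way under a shared measurement model.  The configured
#' arbiter decides when the difference test and the criteria disagree;
#' the disagreement itself is always recorded.
#'
#' @param panel a [response_panel()].
#' @param S class count (typically the Step 2 selection).
#' @param config a [framework_config()].
#' @param test_groups also test group homogeneity of delta and tau
#'   (needs `panel$group`).
#' @return A `step3_result` with `transition` (comparison or note),
#'   optional `group_delta` / `group_tau`, and `selected_spec`.
#' @export
step3_invariance_tests <- function(panel, S, config = framework_config(),
                                   test_groups = FALSE) {
  t_occ <- n_occasions(panel)
  out <- list()
  base_args <- list(S = S, starts = config$starts_lta, tol = config$tol,
                    max_iter = config$max_iter)
  transition_invariance <- FALSE
  if (t_occ < 3L) {
    out$transition <- paste(
      "transition-probability invariance not testable with",
      t_occ, "occasions (a single transition matrix); test skipped")
  } else {
    fit_free <- suppressWarnings(fit_lta(panel, do.call(lta_spec, c(
      base_args, list(seed = config$seed + 40000L)))))
    fit_invt <- suppressWarnings(fit_lta(panel, do.call(lta_spec, c(
      base_args, list(transition_invariance = TRUE,
                      seed = config$seed + 50000L)))))
    cmp <- lrdt(fit_invt, fit_free, alpha = config$alpha,
                arbiter = config$arbiter)
    out$transition <- cmp
    out$fit_free <- fit_free
    out$fit_invariant <- fit_invt
    transition_invariance <- cmp$decision == "restricted_retained"
  }
  if (test_groups) {
    if (is.null(panel$group)) stop("group tests need a grouped panel")
    fit_hom <- suppressWarnings(fit_lta(panel, do.call(lta_spec, c(
      base_args, list(transition_invariance = transition_invariance,
                      seed = config$seed + 60000L)))))
    fit_dvar <- suppressWarnings(fit_lta(panel, do.call(lta_spec, c(
      base_args, list(transition_invariance = transition_invariance,
                      group = list(delta_varies = TRUE),
                      seed = config$seed + 70000L)))))
    out$group_delta <- lrdt(fit_hom, fit_dvar, alpha = config$alpha,
                            arbiter = config$arbiter)
    fit_tvar <- suppressWarnings(fit_lta(panel, do.call(lta_spec, c(
      base_args, list(transition_invariance = transition_invariance,
                      group = list(delta_varies = TRUE, tau_varies = TRUE),
                      seed = config$seed + 80000L)))))
    out$group_tau <- lrdt(fit_dvar, fit_tvar, alpha = config$alpha,
                          arbiter = config$arbiter)
  }
  out$selected_spec <- do.call(lta_spec, c(
    base_args, list(transition_invariance = transition_invariance,
                    seed = config$seed + 40000L)))
  structure(out, class = "step3_result")
}

#' Step 4: covariates on the latent structure
#'
#' Adds the configured covariates to the selected model's first-occasion
#' prevalences (one-step estimation) and tests their joint effect by the
#' likelihood-ratio difference test.  When transition covariates are
#' requested, a sparseness failure -- expected origin-to-destination
#' counts too thin to support the logits -- is reported as a finding of
#' the step, not an error: thin transition cells are a property of the
#' data worth reporting.
#'
#' @param panel a [response_panel()] carrying the covariate columns.
#' @param spec the selected [lta_spec()] (from Step 3).
#' @param covariates covariate column names.
#' @param config a [framework_config()].
#' @param base_fit optional covariate-free fit to reuse.
#' @return A `step4_result`: `fit_base`, `fit_covariate`, `effect_test`,
#'   `odds_ratios`, and `transition_finding` (NULL, a fit, or the
#'   sparseness message).
#' @export
step4_covariates <- function(panel, spec, covariates,
                             config = framework_config(),
                             base_fit = NULL) {
  if (length(covariates) == 0L)
    return(structure(list(skipped = "no covariates supplied"),
                     class = "step4_result"))
  if (is.null(base_fit))
    base_fit <- suppressWarnings(fit_lta(panel, spec))
  spec_cov <- spec
  spec_cov$covariates <- covariates
  fit_cov <- suppressWarnings(
    fit_lta_covariates(panel, spec_cov, base_fit = base_fit))
  eff <- covariate_effect_test(fit_cov, base_fit, alpha = config$alpha)
  transition_finding <- NULL
  if (isTRUE(config$covariate_on_transitions)) {
    spec_ct <- spec_cov
    spec_ct$covariate_on_transitions <- TRUE
    transition_finding <- tryCatch(
      suppressWarnings(fit_lta_covariates(panel, spec_ct,
                                          base_fit = base_fit)),
      lta_sparseness_error = function(e) conditionMessage(e),
      lta_estimation_error = function(e) conditionMessage(e))
  }
  structure(
    list(fit_base = base_fit, fit_covariate = fit_cov, effect_test = eff,
         odds_ratios = odds_ratios(fit_cov),
         transition_finding = transition_finding),
    class = "step4_result")
}

#' Run the staged model-building workflow
#'
#' Executes Steps 0 through 4 in order -- cross-sectional candidate pool,
#' longitudinal measurement invariance, status definition, transition
#' (and group) invariance, covariates -- recording every fit statistic,
#' comparison and decision along the way.  The run is deterministic given
#' (data, config): every fit's seed derives from the config seed.  A
#' step's hard failure stops the run and returns the partial report with
#' the error recorded.  Rerunning with counts added to `exclude` is the
#' supported way to "go back and pick another candidate".  Distal
#' outcomes (a Step 5) are outside this workflow's scope; the report
#' carries an explicit placeholder saying so.
#'
#' @param panel a [response_panel()].
#' @param config a [framework_config()].
#' @return A `framework_report`.
#' @export
run_framework <- function(panel, config = framework_config()) {
  report <- list(config = config, warnings = character(0),
                 step5 = "distal outcomes: not implemented in this workflow")
  grab <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      report$warnings <<- c(report$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  finish <- function(report, error = NULL) {
    report$error <- error
    structure(report, class = "framework_report")
  }
  res <- tryCatch({
    report$step0 <- grab(step0_candidate_pool(panel, config = config))
    report$step1 <- grab(step1_measurement_invariance(
      panel, report$step0, config = config))
    if (length(report$step1$surviving) == 0L)
      return(finish(report))
    report$step2 <- grab(step2_define_statuses(
      report$step1, threshold = config$highlight_threshold,
      labels = config$labels,
      criterion = config$selection_criterion))
    s_sel <- report$step2$selection$selected %||% report$step2$fit$S
    report$step3 <- grab(step3_invariance_tests(
      panel, s_sel, config = config,
      test_groups = !is.null(panel$group)))
    report$selected_spec <- report$step3$selected_spec
    sel_fit <- if (report$selected_spec$transition_invariance)
      report$step3$fit_invariant
    else report$step3$fit_free %||% report$step2$fit
    report$selected_fit <- sel_fit
    if (length(config$covariates) > 0L)
      report$step4 <- grab(step4_covariates(
        panel, report$selected_spec, config$covariates, config = config,
        base_fit = sel_fit))
    finish(report)
  }, error = function(e) finish(report, conditionMessage(e)))
  res
}

#' @export
print.framework_report <- function(x, ...) {
  cat("Latent transition model-building report\n")
  cat("=======================================\n")
  if (!is.null(x$step0)) {
    cat("\nStep 0 - candidate pool:",
        paste(x$step0$pool, collapse = ", "), "\n")
  }
  if (!is.null(x$step1)) {
    for (r in x$step1$results) {
      if (!is.null(r$error)) {
        cat(sprintf("Step 1 - S = %d: estimation failed (%s)\n", r$S, r$error))
      } else
        cat(sprintf(
          "Step 1 - S = %d: G2_delta = %.2f on %d df, p = %.4f -> invariance %s\n",
          r$S, r$comparison$G2_delta, r$comparison$df_delta,
          r$comparison$p_value,
          if (r$survives) "retained" else "rejected"))
    }
    if (!is.null(x$step1$fallback)) cat(x$step1$fallback, "\n")
  }
  if (!is.null(x$step2)) {
    sel <- x$step2$selection
    if (!is.null(sel))
      cat(sprintf("Step 2 - selected S = %d by %s%s\n", sel$selected,
                  sel$criterion,
                  if (sel$conflict) " [BIC disagrees]" else ""))
    print(x$step2)
  }
  if (!is.null(x$step3)) {
    if (is.character(x$step3$transition)) {
      cat("Step 3 -", x$step3$transition, "\n")
    } else {
      cmp <- x$step3$transition
      cat(sprintf(
        "Step 3 - transition invariance: G2_delta = %.2f on %d df, p = %.4f -> %s%s\n",
        cmp$G2_delta, cmp$df_delta, cmp$p_value, cmp$decision,
        if (cmp$conflict) " [criteria conflict]" else ""))
    }
  }
  if (!is.null(x$step4) && is.null(x$step4$skipped)) {
    eff <- x$step4$effect_test
    cat(sprintf(
      "Step 4 - covariate effect on prevalences: G2_delta = %.2f on %d df, p = %.4f\n",
      eff$G2_delta, eff$df_delta, eff$p_value))
    if (is.character(x$step4$transition_finding))
      cat("Step 4 - transition covariates:", x$step4$transition_finding, "\n")
  }
  cat("Step 5 -", x$step5, "\n")
  if (!is.null(x$error)) cat("run terminated early:", x$error, "\n")
  if (length(x$warnings))
    cat(sprintf("(%d warnings recorded)\n", length(x$warnings)))
  invisible(x)
}

#' Export a framework report
#'
#' Writes a machine-readable JSON manifest and a human-readable Markdown
#' summary with embedded CSV-style tables (the fit-statistic grid, the
#' status profile, prevalences and transition matrices, covariate
#' coefficients).  Output is deterministic given the report.
#'
#' @param report a `framework_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  manifest <- list(
    config = unclass(report$config),
    pool = report$step0$pool,
    grid = report$step0$grid,
    step1 = lapply(report$step1$results, function(r)
      if (!is.null(r$error)) list(S = r$S, error = r$error)
      else list(S = r$S, G2_delta = r$comparison$G2_delta,
                df_delta = r$comparison$df_delta,
                p = r$comparison$p_value, survives = r$survives)),
    selected_S = report$step2$selection$selected %||%
      report$step2$fit$S %||% NULL,
    warnings = report$warnings, error = report$error,
    step5 = report$step5)
  if (!is.null(report$selected_fit)) {
    f <- report$selected_fit
    manifest$loglik <- f$loglik
    manifest$stats <- f$stats[c("G2", "P", "df", "AIC", "BIC", "CAIC",
                                "ABIC", "N_effective")]
    manifest$delta <- f$delta
    manifest$tau <- f$tau
  }
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  md <- c("# Latent transition model-building report", "")
  if (!is.null(report$step0))
    md <- c(md, "## Step 0: candidate pool", "",
            paste("Pool:", paste(report$step0$pool, collapse = ", ")), "",
            df_to_md(report$step0$grid))
  if (!is.null(report$error))
    md <- c(md, "", paste("Run terminated early:", report$error))
  if (!is.null(report$step2)) {
    md <- c(md, "", "## Status profile", "",
            df_to_md(as.data.frame(round(report$step2$profile, 4))))
  }
  if (!is.null(report$selected_fit)) {
    f <- report$selected_fit
    md <- c(md, "", "## Prevalences (model-implied)", "",
            df_to_md(as.data.frame(round(f$occupancy, 4))))
    for (t in seq_along(f$tau)) {
      tm <- f$tau[[t]]
      if (is.list(tm)) tm <- tm[[1L]]
      md <- c(md, "", sprintf("## Transition matrix %d -> %d", t, t + 1L),
              "", df_to_md(as.data.frame(round(tm, 4))))
    }
  }
  if (!is.null(report$step4) && !is.null(report$step4$odds_ratios)) {
    md <- c(md, "", "## Covariate odds ratios (reference: status 1)", "",
            df_to_md(as.data.frame(round(report$step4$odds_ratios, 4))))
  }
  md <- c(md, "", "## Step 5", "", report$step5)
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}

df_to_md <- function(df) {
  df <- cbind(" " = rownames(df), df)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r)
    paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, unname(rows))
}
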