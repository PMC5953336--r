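# Independent oracles and small fixture builders used across the suite.

# well-separated binary-item truths for recovery checks
crisp_truth <- function(S = 3L, T_occ = 3L, J = 6L, N = 600L,
                        hi = 0.9, lo = 0.1, stay = 0.8) {
  p <- matrix(lo, S, J)
  for (s in seq_len(S)) {
    on <- seq_len(J) <= round(J * (S - s + 1) / S)
    p[s, on] <- hi
  }
  tr <- matrix((1 - stay) / (S - 1), S, S)
  diag(tr) <- stay
  d <- rev(seq_len(S)); d <- d / sum(d)
  lta_truth(S, T_occ, 2L, rho = p, delta = d, tau = tr, N = N)
}

# brute-force joint-pattern likelihood by enumerating all S^T status
# sequences; rho_list has one S x J x C array per occasion
enumerate_loglik <- function(rows, delta, tau, rho_list) {
  S <- length(delta); T_occ <- length(rho_list)
  J <- dim(rho_list[[1L]])[2L]
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), T_occ)))
  ll <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    tot <- 0
    for (r in seq_len(nrow(seqs))) {
      s <- seqs[r, ]
      p <- delta[s[1L]]
      if (T_occ > 1L) for (t in 2L:T_occ) p <- p * tau[[t - 1L]][s[t - 1L], s[t]]
      for (t in seq_len(T_occ)) for (j in seq_len(J)) {
        code <- rows[i, (t - 1L) * J + j]
        if (!is.na(code)) p <- p * rho_list[[t]][s[t], j, code]
      }
      tot <- tot + p
    }
    ll[i] <- log(tot)
  }
  ll
}

# brute-force per-occasion marginal posteriors by sequence enumeration
enumerate_posteriors <- function(rows, delta, tau, rho_list) {
  S <- length(delta); T_occ <- length(rho_list)
  J <- dim(rho_list[[1L]])[2L]
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), T_occ)))
  marg <- array(0, dim = c(nrow(rows), S, T_occ))
  for (i in seq_len(nrow(rows))) {
    pr <- numeric(nrow(seqs))
    for (r in seq_len(nrow(seqs))) {
      s <- seqs[r, ]
      p <- delta[s[1L]]
      if (T_occ > 1L) for (t in 2L:T_occ) p <- p * tau[[t - 1L]][s[t - 1L], s[t]]
      for (t in seq_len(T_occ)) for (j in seq_len(J)) {
        code <- rows[i, (t - 1L) * J + j]
        if (!is.na(code)) p <- p * rho_list[[t]][s[t], j, code]
      }
      pr[r] <- p
    }
    pr <- pr / sum(pr)
    for (t in seq_len(T_occ)) for (s in seq_len(S))
      marg[i, s, t] <- sum(pr[seqs[, t] == s])
  }
  marg
}

# wrap a raw code matrix as a pattern_table (unit frequencies by default)
as_pattern_table <- function(rows, n_cat, T_occ, freq = NULL) {
  J <- ncol(rows) / T_occ
  n_cat <- rep_len(as.integer(n_cat), J)
  if (is.null(freq)) freq <- rep(1L, nrow(rows))
  structure(
    list(patterns = rows, freq = as.integer(freq),
         W = prod(n_cat)^T_occ,
         n_categories = rep(n_cat, T_occ), item_categories = n_cat,
         n_items = J, n_occasions = T_occ,
         items = paste0("item", seq_len(J)),
         respondent_pattern = rep(seq_len(nrow(rows)), freq),
         N = sum(freq)),
    class = "pattern_table")
}

# mean absolute difference of aligned parameter sets
aligned_mae <- function(fit, truth) {
  al <- align_statuses(fit$rho, truth$rho[[1L]])
  perm <- al$permutation
  rho_f <- fit$rho
  rho_t <- truth$rho[[1L]][perm, , , drop = FALSE]
  d_t <- truth$delta[perm]
  tau_t <- lapply(truth$tau, function(m) m[perm, perm])
  c(rho = mean(abs(rho_f - rho_t)),
    delta = mean(abs(fit$delta - d_t)),
    tau = mean(abs(unlist(fit$tau) - unlist(tau_t))))
}

# random parameter sets and a fixed-parameter E-step (single EM pass whose
# reported log-likelihood is evaluated at the supplied parameters)
make_params <- function(S, T_occ, J, seed) {
  set.seed(seed)
  rho_list <- lapply(seq_len(T_occ), function(t) {
    a <- array(stats::runif(S * J * 2, 0.05, 0.95), dim = c(S, J, 2))
    a[, , 2] <- 1 - a[, , 1]
    a
  })
  d <- stats::rgamma(S, 1); d <- d / sum(d)
  tau <- lapply(seq_len(T_occ - 1L), function(t) {
    m <- matrix(stats::rgamma(S * S, 1), S, S) + diag(S)
    m / rowSums(m)
  })
  list(rho_list = rho_list, delta = d, tau = tau)
}

fixed_param_estep <- function(rows, w, par, S, T_occ, J,
                              measurement_invariance = FALSE) {
  pt <- as_pattern_table(rows, 2, T_occ, freq = w)
  prep <- list(table = pt, rows = rows, w = as.numeric(w), X = NULL,
               row_group = rep(1L, nrow(rows)), n_groups = 1L,
               T_occ = T_occ, J = J, cj = rep(2L, J), n_eff = sum(w))
  spec <- lta_spec(S, measurement_invariance = measurement_invariance,
                   max_iter = 1L)
  init <- list(rho_sets = if (measurement_invariance) par$rho_list[1L]
                          else par$rho_list,
               delta = matrix(par$delta, 1L),
               tau = lapply(par$tau, list))
  em_lta(prep, spec, init)
}
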