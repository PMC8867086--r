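#' Project a symmetric matrix to the nearest positive-definite correlation
#' matrix
#'
#' Eigenvalues are clipped from below at `eps`, the matrix reassembled and
#' rescaled to unit diagonal.  Used when a group effect or state
#' perturbation pushes a constructed correlation matrix outside the
#' positive-definite cone.
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @return A positive-definite matrix with unit diagonal.
#' @export
nearest_pd <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

#' Sample matrix-variate normal draws with equal factors
#'
#' Draws `W = M + A Z A'` where `A` is the symmetric square root of the
#' positive-semidefinite factor `C` and `Z` has independent standard-normal
#' entries, so that `vec(W)` has covariance `C %x% C`.
#'
#' @param M Mean matrix (n x n).
#' @param C Positive-semidefinite factor (n x n).
#' @param n_draws Number of samples.
#' @param seed Integer seed.
#' @return An `n x n x n_draws` array.
#' @export
#' @examples
#' w <- sample_matrix_normal(diag(2), diag(2), 5, seed = 1)
#' dim(w)
sample_matrix_normal <- function(M, C, n_draws, seed) {
  M <- as.matrix(M); C <- as.matrix(C)
  n <- nrow(M)
  stopifnot(nrow(C) == n, ncol(C) == n, ncol(M) == n)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    abort("C must be positive semi-definite", class = "hierfcn_validation")
  }
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  set.seed(seed %% .Machine$integer.max)
  out <- array(0, dim = c(n, n, n_draws))
  for (k in seq_len(n_draws)) {
    Z <- matrix(rnorm(n * n), n, n)
    out[, , k] <- M + A %*% Z %*% t(A)
  }
  out
}

#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of ROI time series with block-structured correlation:
#' within-network pairs correlate at `rho_within`, between-network pairs at
#' `rho_between`.  Optional state switching makes the correlation dynamic:
#' time is divided into fixed dwell segments cycling through `n_states`
#' states whose within-network correlation is offset by equally spaced
#' values in `[-state_amp, state_amp]`.  The patient group's within-network
#' correlations in `effect_network` are additionally shifted by
#' `effect_delta` (then projected back to the nearest positive-definite
#' correlation matrix), emulating a connectivity-level group difference.
#'
#' @param n_per_group Number of patients (+1 class).
#' @param n_controls Number of controls (-1 class); defaults to
#'   `n_per_group`.
#' @param M_time Time points per subject.
#' @param partition A [subnet_partition].
#' @param rho_within,rho_between Baseline correlations,
#'   `0 <= rho_between <= rho_within < 1`.
#' @param effect_network Name of the perturbed sub-network (or `NULL`).
#' @param effect_delta Correlation shift applied to the patient group's
#'   within-`effect_network` edges (0 disables the effect).
#' @param n_states Number of correlation states (>= 1).
#' @param state_dwell Dwell length of each state in time points.
#' @param state_amp Half-range of the state offsets on the correlation
#'   scale.
#' @param noise_sd Standard deviation of additive measurement noise.
#' @param seed Integer seed.
#' @return A `cohort_spec` object (with precomputed per-state, per-group
#'   correlation matrices).
#' @export
cohort_spec <- function(n_per_group = 30L, n_controls = n_per_group,
                        M_time = 120L, partition,
                        rho_within = 0.5, rho_between = 0.1,
                        effect_network = NULL, effect_delta = 0,
                        n_states = 2L, state_dwell = 30L, state_amp = 0.1,
                        noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(partition, "subnet_partition"))
  if (!(rho_between >= 0 && rho_between <= rho_within && rho_within < 1)) {
    abort("need 0 <= rho_between <= rho_within < 1", class = "hierfcn_validation")
  }
  if (n_states < 1L || state_dwell < 2L) {
    abort("need n_states >= 1 and state_dwell >= 2", class = "hierfcn_validation")
  }
  if (!is.null(effect_network) && !effect_network %in% names(partition)) {
    abort(paste0("effect_network '", effect_network, "' not in the partition"),
          class = "hierfcn_validation")
  }
  n_roi <- length(unlist(partition))
  offsets <- if (n_states == 1L) 0 else seq(-state_amp, state_amp, length.out = n_states)

  base_matrix <- function(rw) {
    m <- matrix(rho_between, n_roi, n_roi)
    for (idx in partition) m[idx, idx] <- rw
    diag(m) <- 1
    m
  }
  states <- lapply(seq_len(n_states), function(s) {
    rw <- rho_within + offsets[s]
    if (rw >= 1 || rw < rho_between) {
      abort(sprintf("state %d within-network correlation %.3f invalid (rho_within %.2f, state_amp %.2f)",
                    s, rw, rho_within, state_amp), class = "hierfcn_validation")
    }
    ctrl <- base_matrix(rw)
    ev <- min(eigen(ctrl, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      abort(sprintf("state %d control correlation matrix not positive definite (min eigenvalue %.2e); adjust rho_within/rho_between",
                    s, ev), class = "hierfcn_numeric")
    }
    pat <- ctrl
    if (!is.null(effect_network) && effect_delta != 0) {
      idx <- partition[[effect_network]]
      off <- matrix(effect_delta, length(idx), length(idx))
      diag(off) <- 0
      pat[idx, idx] <- pat[idx, idx] + off
      pat <- pmin(pmax(pat, -0.99), 0.99)
      diag(pat) <- 1
      pat <- nearest_pd(pat)
    }
    list(control = ctrl, patient = pat)
  })

  structure(list(n_per_group = as.integer(n_per_group),
                 n_controls = as.integer(n_controls),
                 M_time = as.integer(M_time), partition = partition,
                 rho_within = rho_within, rho_between = rho_between,
                 effect_network = effect_network, effect_delta = effect_delta,
                 n_states = as.integer(n_states),
                 state_dwell = as.integer(state_dwell), state_amp = state_amp,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 states = states, n_roi = n_roi),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d + %d subjects, %d time points, %d ROIs, %d state(s)\n",
              x$n_per_group, x$n_controls, x$M_time, x$n_roi, x$n_states))
  if (!is.null(x$effect_network) && x$effect_delta != 0) {
    cat(sprintf("  group effect: %+.2f on within-%s edges\n",
                x$effect_delta, x$effect_network))
  }
  invisible(x)
}

#' Generate a synthetic two-group cohort of ROI time series
#'
#' Per subject, time is split into fixed dwell segments cycling through the
#' correlation states; each segment's rows are drawn from a multivariate
#' normal with the (group- and state-specific) correlation matrix, and
#' independent Gaussian measurement noise is added.  Identical spec and
#' seed give a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List with `timeseries` (list of [roi_ts]), `labels` (tibble,
#'   patients +1 first), and `ground_truth` (effect network/edges, state
#'   sequence, generator parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rn <- attr(spec$partition, "roi_names")
  if (is.null(rn)) rn <- paste0("roi", seq_len(spec$n_roi))
  chols <- lapply(spec$states, function(s) {
    list(control = chol(s$control), patient = chol(s$patient))
  })
  state_seq <- rep(rep_len(seq_len(spec$n_states),
                           ceiling(spec$M_time / spec$state_dwell)),
                   each = spec$state_dwell)[seq_len(spec$M_time)]
  n_total <- spec$n_per_group + spec$n_controls
  ids <- sprintf("S%03d", seq_len(n_total))
  labels <- tibble(subject_id = ids,
                   label = rep(c(1L, -1L), c(spec$n_per_group, spec$n_controls)))
  set.seed(spec$seed %% .Machine$integer.max)
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    grp <- if (labels$label[i] > 0) "patient" else "control"
    vals <- matrix(0, spec$M_time, spec$n_roi)
    for (s in unique(state_seq)) {
      rows <- which(state_seq == s)
      Z <- matrix(rnorm(length(rows) * spec$n_roi), length(rows), spec$n_roi)
      vals[rows, ] <- Z %*% chols[[s]][[grp]]
    }
    if (spec$noise_sd > 0) {
      vals <- vals + matrix(rnorm(length(vals), sd = spec$noise_sd),
                            nrow(vals), ncol(vals))
    }
    subjects[[i]] <- roi_ts(vals, roi_names = rn, subject_id = ids[i])
  }
  effect_edges <- if (!is.null(spec$effect_network) && spec$effect_delta != 0) {
    idx <- spec$partition[[spec$effect_network]]
    pairs <- t(utils::combn(idx, 2))
    tibble(roi_i = rn[pairs[, 2]], roi_j = rn[pairs[, 1]],
           delta = spec$effect_delta)
  } else {
    tibble(roi_i = character(0), roi_j = character(0), delta = numeric(0))
  }
  list(timeseries = subjects, labels = labels,
       ground_truth = list(effect_network = spec$effect_network,
                           effect_delta = spec$effect_delta,
                           effect_edges = effect_edges,
                           state_sequence = state_seq,
                           rho_within = spec$rho_within,
                           rho_between = spec$rho_between,
                           seed = spec$seed))
}
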