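# Small fixtures shared across test files; all generated in code.

# a minimal phantom with no optional structure: clean module + global + noise
plain_phantom <- function(dims = c(5, 5, 4), n_modules = 2, seed = 11) {
  generate_phantom(dims, n_modules = n_modules, wm_adjacent_fraction = 0,
                   seed = seed, midline_fraction = 0, bridge_fraction = 0)
}

# a signal model with every optional loading disabled, so the closed-form
# population correlations hold exactly
plain_model <- function(t = 120, var_module = 1, var_noise = 1, var_global = 1,
                        seed = 21, ...) {
  signal_model(t = t, var_module = var_module, var_noise = var_noise,
               var_global = var_global, var_wm = 0, var_vent = 0,
               vent_gray_amp = 0, midline_global_amp = 1,
               boundary_mixing = 0, var_local = 0,
               seed = seed, ...)
}

# hand-built ts_data wrapping a bare matrix (aux series optional)
matrix_dataset <- function(data, tr = 2.5, aux = NULL, aux_label = NULL,
                           motion = NULL) {
  t_len <- ncol(data)
  structure(list(
    data = data,
    aux = if (is.null(aux)) matrix(numeric(0), 0, t_len) else aux,
    aux_label = if (is.null(aux_label)) character(0) else aux_label,
    motion = if (is.null(motion)) matrix(0, 6, t_len) else motion,
    tr = tr, t = t_len,
    tissue = rep("gray", nrow(data)),
    true_module = rep(1L, nrow(data)),
    second_module = rep(NA_integer_, nrow(data)),
    midline = rep(FALSE, nrow(data)),
    coords = cbind(seq_len(nrow(data)) - 1L, 0L, 0L),
    latent = NULL, model = NULL,
    provenance = "test fixture"
  ), class = "ts_data")
}

# corr_matrix from an explicit symmetric matrix
matrix_corr <- function(values, t = 120) {
  structure(list(values = values, n = nrow(values), t = t,
                 n_offdiagonal = nrow(values) * (nrow(values) - 1)),
            class = "corr_matrix")
}

# exhaustive S-threshold oracle: try every distinct positive value (plus a
# cut below the minimum) as a strict-> threshold and pick the best S
oracle_threshold <- function(values, S_target) {
  n <- nrow(values)
  vals <- values[upper.tri(values)]
  pos <- sort(unique(vals[vals > 0]))
  cands <- c(pos[1] / 2, pos)
  best <- NULL
  for (thr in cands) {
    E <- sum(vals > thr)
    K <- 2 * E / n
    if (K <= 1) next
    S <- log(n) / log(K)
    if (is.null(best) || abs(S - S_target) <= best$gap + 1e-15) {
      # ties toward larger threshold: later candidates win on equality
      if (is.null(best) || abs(S - S_target) < best$gap - 1e-15 ||
          thr > best$thr) {
        best <- list(thr = thr, S = S, K = K, E = E,
                     gap = abs(S - S_target))
      }
    }
  }
  best
}
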