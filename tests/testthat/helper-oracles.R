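# Independent oracles: deliberately naive implementations used only to check
# the package's vectorised/production code paths.

# exhaustive per-cell scan for strict 8-neighbour local maxima outside the
# scatter band, with the same prominence filter and ordering as the package
brute_force_peaks <- function(e, ridge_halfwidth_nm = 10, min_prominence = 0.05) {
  m <- e$intensity
  gmax <- max(m)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      strict_max <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] >= m[i, j]) {
            strict_max <- FALSE
          }
        }
      }
      in_band <- abs(e$excitation_nm[i] - e$emission_nm[j]) <= ridge_halfwidth_nm
      if (strict_max && !in_band && m[i, j] >= min_prominence * gmax) {
        rows[[length(rows) + 1]] <- data.frame(
          excitation_nm = e$excitation_nm[i],
          emission_nm = e$emission_nm[j],
          intensity = m[i, j]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(excitation_nm = numeric(0), emission_nm = numeric(0),
                      intensity = numeric(0)))
  }
  out[order(-out$intensity, out$excitation_nm, out$emission_nm), , drop = FALSE]
}

# brute-force maximum over in-band cells, same tie-break as the package
brute_force_ridge_max <- function(e, ridge_halfwidth_nm = 10) {
  best <- NULL
  for (i in seq_along(e$excitation_nm)) {
    for (j in seq_along(e$emission_nm)) {
      if (abs(e$excitation_nm[i] - e$emission_nm[j]) <= ridge_halfwidth_nm) {
        v <- e$intensity[i, j]
        if (is.null(best) || v > best$intensity) {
          best <- list(excitation_nm = e$excitation_nm[i],
                       emission_nm = e$emission_nm[j], intensity = v)
        }
      }
    }
  }
  best
}

# closed-form normal equations, independent of stats::lm
closed_form_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

# Spearman with midranks written out as Pearson on ranks
midrank_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

random_eem <- function(n_ex, n_em, seed) {
  set.seed(seed)
  eem(seq(200, by = 5, length.out = n_ex),
      seq(270, by = 5, length.out = n_em),
      matrix(runif(n_ex * n_em, 0, 1000), n_ex, n_em))
}
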