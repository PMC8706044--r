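# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive results with naive enumeration rather than
# calling back into the vectorized package implementations.

# Random per-injection feature tables with clustered coordinates so that
# replicate groups within tolerance exist alongside near-misses.
random_injection_tables <- function(seed, n_clusters = 8, n_inj = 3,
                                    p_present = 0.8, sample = "S",
                                    instrument = "B") {
  withr::with_seed(seed, {
    centers_mz <- runif(n_clusters, 100, 500)
    centers_rt <- runif(n_clusters, 5, 34)
    base_int <- runif(n_clusters, 100, 1e5)
    tabs <- lapply(seq_len(n_inj), function(j) {
      present <- runif(n_clusters) < p_present
      idx <- which(present)
      n <- length(idx)
      data.frame(
        feature_id = sprintf("f%d_%d", j, seq_len(max(n, 0))),
        mz = centers_mz[idx] * (1 + rnorm(n, 0, 3) * 1e-6),
        rt = centers_rt[idx] + rnorm(n, 0, 0.15),
        intensity = base_int[idx] * runif(n, 0.5, 2),
        sample = rep(sample, n), injection = rep(j, n),
        instrument = rep(instrument, n),
        stringsAsFactors = FALSE
      )
    })
    tabs
  })
}

# Exhaustive consensus-grouping oracle: seeds groups at the globally most
# intense unused feature (ties by ascending m/z), enumerates every
# cross-injection tuple of unused in-tolerance features, and accepts the
# tuple minimizing total |mz - seed mz| (ties by total |rt - seed rt|).
consensus_oracle <- function(tables, tol) {
  n_inj <- length(tables)
  rows <- list()
  for (j in seq_along(tables)) {
    tb <- tables[[j]]
    for (r in seq_len(nrow(tb))) {
      if (tb$intensity[r] >= tol$noise_threshold) {
        rows[[length(rows) + 1]] <-
          list(mz = tb$mz[r], rt = tb$rt[r], intensity = tb$intensity[r],
               inj = j)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(mz = numeric(), rt = numeric(), intensity = numeric()))
  mzv <- vapply(rows, `[[`, 1, "mz")
  rtv <- vapply(rows, `[[`, 1, "rt")
  iv <- vapply(rows, `[[`, 1, "intensity")
  jv <- vapply(rows, `[[`, 1, "inj")
  ord <- order(-iv, mzv)
  used <- rep(FALSE, length(rows))
  out <- list()
  for (s in ord) {
    if (used[s]) next
    in_tol <- !used &
      abs((mzv[s] - mzv) / mzv[s] * 1e6) <= tol$ppm_tol &
      abs(rtv - rtv[s]) <= tol$rt_tol
    cand <- lapply(seq_len(n_inj), function(j) {
      if (j == jv[s]) return(s)
      which(in_tol & jv == j)
    })
    used[s] <- TRUE
    if (any(vapply(cand, length, 1L) == 0)) next
    tuples <- as.matrix(expand.grid(cand))
    cost_mz <- rowSums(matrix(abs(mzv[tuples] - mzv[s]), nrow(tuples)))
    cost_rt <- rowSums(matrix(abs(rtv[tuples] - rtv[s]), nrow(tuples)))
    pick <- tuples[order(cost_mz, cost_rt)[1], ]
    used[pick] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      mz = mean(mzv[pick]), rt = mean(rtv[pick]),
      intensity = mean(iv[pick]))
  }
  if (length(out) == 0)
    return(data.frame(mz = numeric(), rt = numeric(), intensity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$mz), , drop = FALSE]
}

# Naive blank-subtraction oracle (double loop).
blank_subtract_oracle <- function(features, blank, tol) {
  keep <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(features))) {
    for (b in seq_len(nrow(blank))) {
      if (abs((features$mz[i] - blank$mz[b]) / features$mz[i] * 1e6) <= tol$ppm_tol &&
          abs(features$rt[i] - blank$rt[b]) <= tol$rt_tol) {
        keep[i] <- FALSE
        break
      }
    }
  }
  features[keep, , drop = FALSE]
}

# Brute-force mass screen oracle: loop over every compound.
mass_screen_oracle <- function(mz, db, ppm_window) {
  ids <- character(0); scores <- numeric(0)
  for (i in seq_len(nrow(db))) {
    ppm <- (db$adduct_mass[i] - mz) / db$adduct_mass[i] * 1e6
    if (abs(ppm) <= ppm_window) {
      ids <- c(ids, db$compound_id[i])
      scores <- c(scores, 1 - abs(ppm) / ppm_window)
    }
  }
  data.frame(compound_id = ids, mass_subscore = scores,
             stringsAsFactors = FALSE)
}

# Tiny consensus-like feature data.frame for scoring tests.
make_features <- function(mz, rt, column, intensity = 1000,
                          sample = "S", instrument = "B") {
  n <- length(mz)
  data.frame(feature_id = sprintf("F%03d", seq_len(n)), mz = mz, rt = rt,
             intensity = rep_len(intensity, n), column = column,
             sample = rep_len(sample, n), instrument = rep_len(instrument, n),
             stringsAsFactors = FALSE)
}

# Small compound database built by hand.
make_db <- function(mass, logd, families, fragments = NULL) {
  n <- length(mass)
  if (is.null(fragments)) fragments <- lapply(mass, function(m) c(m - 20, m - 50))
  db <- data.frame(compound_id = sprintf("C%03d", seq_len(n)),
                   name = sprintf("cmp%03d", seq_len(n)),
                   monoisotopic_mass = mass,
                   adduct_mass = mass + polarscreen::PROTON_MASS,
                   logd_ph7 = logd,
                   literature_tag = "test",
                   stringsAsFactors = FALSE)
  db$families <- I(families)
  db$fragments <- I(fragments)
  db
}

# Two-class Gaussian matrix with informative features (class mean shift
# delta on the first n_inf features).
separated_classes <- function(seed, n_per_class = 15, n_inf = 10,
                              n_noise = 90, delta = 5) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    cls <- rep(c("a", "b"), each = n_per_class)
    X <- matrix(rnorm(n * (n_inf + n_noise)), n)
    X[cls == "b", seq_len(n_inf)] <- X[cls == "b", seq_len(n_inf)] + delta
    list(X = X, classes = cls)
  })
}
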