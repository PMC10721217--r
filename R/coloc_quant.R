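# Quantification of synaptic labeling: anisotropic apposition detection on
# puncta point sets, per-neuron colocalization fractions (the neuron is the
# statistical unit), background-corrected SF, and Wilcoxon rank-sum
# comparisons.

#' Detect pre/postsynaptic appositions in 3D point sets
#'
#' A PSD point is apposed iff a presynaptic point lies within the
#' axis-aligned anisotropic ellipsoid
#' `(dx^2 + dy^2)/lateral_tol^2 + dz^2/axial_tol^2 <= 1`. Defaults reflect
#' Airyscan resolution limits (~120 nm lateral, ~350 nm axial). Matching is
#' one-to-one, built greedily by ascending normalized distance with
#' deterministic tie-breaking by (distance, PSD index, syn index).
#'
#' @param psd_points,syn_points data.frames with columns `x_um,y_um,z_um`.
#' @param lateral_tol_um,axial_tol_um Tolerances in um, > 0.
#' @return List with `pairs` (data.frame `psd_idx, syn_idx, ndist`) and
#'   `apposed` (logical per PSD point).
#' @export
detect_appositions <- function(psd_points, syn_points,
                               lateral_tol_um = 0.12, axial_tol_um = 0.35) {
  check_positive(lateral_tol_um, "lateral_tol_um")
  check_positive(axial_tol_um, "axial_tol_um")
  np <- nrow(psd_points); ns <- nrow(syn_points)
  empty <- list(pairs = data.frame(psd_idx = integer(0), syn_idx = integer(0),
                                   ndist = numeric(0)),
                apposed = logical(np))
  if (np == 0L || ns == 0L) return(empty)
  stopifnot(all(is.finite(as.matrix(psd_points[, c("x_um", "y_um", "z_um")]))),
            all(is.finite(as.matrix(syn_points[, c("x_um", "y_um", "z_um")]))))

  dx <- outer(psd_points$x_um, syn_points$x_um, `-`)
  dy <- outer(psd_points$y_um, syn_points$y_um, `-`)
  dz <- outer(psd_points$z_um, syn_points$z_um, `-`)
  nd2 <- (dx^2 + dy^2) / lateral_tol_um^2 + dz^2 / axial_tol_um^2
  cand <- which(nd2 <= 1, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- data.frame(psd_idx = cand[, 1L], syn_idx = cand[, 2L],
                     ndist = sqrt(nd2[cand]))
  cand <- cand[order(cand$ndist, cand$psd_idx, cand$syn_idx), ]

  psd_used <- logical(np); syn_used <- logical(ns)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$psd_idx[k]; j <- cand$syn_idx[k]
    if (!psd_used[i] && !syn_used[j]) {
      keep[k] <- TRUE
      psd_used[i] <- TRUE
      syn_used[j] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, apposed = psd_used)
}

#' Per-neuron colocalization fractions and group summaries
#'
#' The per-neuron fraction pools that neuron's segments:
#' `sum(n_apposed) / sum(n_psd)`; group mean and SEM (sd/sqrt(n), sample sd
#' with n-1) are computed over neurons, matching the reported n. Neurons
#' with zero PSDs are excluded with a warning.
#'
#' @param table A `puncta_table` data.frame (see [generate_puncta_table()]).
#' @param group_by Grouping columns (default `"group"`; e.g.
#'   `c("group", "compartment")`).
#' @return data.frame of class `group_summary` with one row per group:
#'   `mean_pct, sem_pct, n_neurons, n_animals`, plus attribute
#'   `"per_neuron"` (data.frame of per-neuron fractions).
#' @export
colocalization_summary <- function(table, group_by = "group") {
  stopifnot(is.data.frame(table),
            all(c("neuron_id", "animal_id", "n_psd", "n_apposed") %in% names(table)),
            all(group_by %in% names(table)))
  if (any(table$n_apposed > table$n_psd) || any(table$n_apposed < 0)) {
    stop("puncta table requires 0 <= n_apposed <= n_psd", call. = FALSE)
  }
  key <- interaction(table[group_by], drop = TRUE, sep = ":")
  per_neuron <- aggregate(table[, c("n_psd", "n_apposed")],
                          by = list(group = key,
                                    neuron_id = table$neuron_id,
                                    animal_id = table$animal_id),
                          FUN = sum)
  zero <- per_neuron$n_psd == 0
  if (any(zero)) {
    warning(sprintf("excluding %d neuron(s) with zero PSD counts: %s",
                    sum(zero),
                    paste(per_neuron$neuron_id[zero], collapse = ", ")))
    per_neuron <- per_neuron[!zero, , drop = FALSE]
  }
  per_neuron$fraction <- per_neuron$n_apposed / per_neuron$n_psd

  groups <- split(per_neuron, per_neuron$group, drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    f <- d$fraction
    data.frame(group = g,
               mean_pct = 100 * mean(f),
               sem_pct = if (length(f) > 1L) 100 * sd(f) / sqrt(length(f)) else 0,
               n_neurons = length(f),
               n_animals = length(unique(d$animal_id)))
  }))
  rownames(out) <- NULL
  attr(out, "per_neuron") <- per_neuron
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Background-corrected synaptic fraction
#'
#' Subtracts the no-glycoprotein background colocalization (starter-to-
#' starter connections and TVA-leak infection) from the with-glycoprotein
#' mean: `SF = (mean_with - mean_without) / 100`. Negative differences are
#' clamped to 0 with a warning.
#'
#' @param mean_with_oG_pct,mean_without_oG_pct Group means in percent.
#' @return SF as a fraction.
#' @examples
#' background_corrected_sf(50.61, 8.86)  # 0.4175 ~ 0.42
#' @export
background_corrected_sf <- function(mean_with_oG_pct, mean_without_oG_pct) {
  for (nm in c("mean_with_oG_pct", "mean_without_oG_pct")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 100) {
      stop_domain(nm, "must be a percentage in [0, 100]")
    }
  }
  sf <- (mean_with_oG_pct - mean_without_oG_pct) / 100
  if (sf < 0) {
    warning("background exceeds signal; clamping SF to 0")
    sf <- 0
  }
  sf
}

# Wilcoxon rank-sum -----------------------------------------------------------

# Exact null counts of the rank-sum W of a sample of size n_a among ranks
# 1..N, by the shift-algorithm recurrence (equivalent to enumerating all
# choose(N, n_a) assignments). counts[w + 1] = number of size-n_a subsets of
# {1..N} with sum w.
rank_sum_counts <- function(n_a, N) {
  max_w <- sum((N - n_a + 1L):N)
  # f[k+1, w+1] after processing ranks 1..r
  f <- matrix(0, nrow = n_a + 1L, ncol = max_w + 1L)
  f[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(n_a, r)
    for (k in kmax:1) {
      w_idx <- (r + 1L):(max_w + 1L)
      f[k + 1L, w_idx] <- f[k + 1L, w_idx] + f[k, w_idx - r]
    }
  }
  f[n_a + 1L, ]
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test on the rank sum W of `a` within the pooled sample. When
#' `n_a + n_b <= 20` and there are no ties, the p-value is exact
#' (`2 * min(P(W <= w), P(W >= w))`, capped at 1) with the null distribution
#' obtained by complete enumeration of rank assignments; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples, nonempty.
#' @return List of class `rank_sum_test` with `statistic` (rank sum of `a`),
#'   `p.value`, `exact` (logical), `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_domain("a/b", "both samples must be nonempty")
  }
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(c(a, b))))
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n_a)])
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && N <= 20L) {
    counts <- rank_sum_counts(n_a, N)
    probs <- counts / sum(counts)  # indexed by w + 1, w = 0..max_w
    p_le <- sum(probs[seq_len(W + 1L)])
    p_ge <- sum(probs[(W + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n_a * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    d <- W - mu
    cc <- sign(d) * 0.5  # continuity correction toward the mean
    z <- if (sigma2 > 0) (d - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = W, p.value = p, exact = exact,
                 n_a = n_a, n_b = n_b),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s): W = %g, n = %d vs %d, p = %.4g\n",
              if (x$exact) "exact" else "normal approximation",
              x$statistic, x$n_a, x$n_b, x$p.value))
  invisible(x)
}

#' Write group summaries and test results as JSON
#'
#' @param summary A `group_summary` (from [colocalization_summary()]).
#' @param tests Optional named list of `rank_sum_test` results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, tests = NULL) {
  stopifnot(inherits(summary, "group_summary"))
  payload <- list(groups = as.data.frame(summary))
  if (!is.null(tests)) {
    payload$tests <- lapply(tests, function(t) {
      list(statistic = t$statistic, p_value = t$p.value, exact = t$exact,
           n_a = t$n_a, n_b = t$n_b)
    })
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
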