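# Closed-form model linking unitary synaptic efficiency (U), synaptic
# multiplicity (M), the input fraction (IF) and the synaptic fraction (SF).
#
# The model assumes rabies crosses each synaptic contact independently with
# probability U, and that a labeled input neuron marks all of its presynaptic
# terminals. For an input neuron making M contacts onto the starter, the
# per-neuron labeling probability is p = 1 - (1 - U)^M. With two input
# populations a and b (counts in ratio R = Na/Nb, multiplicities Ma, Mb):
#
#   IF = (R * pa + pb) / (R + 1)
#   SF = (R * pa * Ma + pb * Mb) / (Ma * R + Mb)

#' Per-neuron labeling probability
#'
#' Probability that an input neuron making `M` synaptic contacts onto a
#' starter cell is labeled, when rabies crosses each contact independently
#' with probability `U`: `p = 1 - (1 - U)^M`.
#'
#' @param U Unitary synaptic efficiency, in \[0, 1\].
#' @param M Number of synaptic contacts (multiplicity), integer >= 1.
#'   May be a vector.
#' @return Labeling probability (vectorized over `M`).
#' @examples
#' labeling_probability(0.28, 1)  # 0.28
#' labeling_probability(0.28, 2)  # 0.4816
#' @export
labeling_probability <- function(U, M) {
  check_probability(U, "U")
  if (!is.numeric(M) || length(M) < 1L || any(!is.finite(M)) ||
      any(M < 1) || any(M != round(M))) {
    stop_domain("M", "must be integer(s) >= 1")
  }
  1 - (1 - U)^M
}

#' Two-population multiplicity model
#'
#' Parameters of the two-population model: input population a (relative
#' count `R`, multiplicity `Ma`) and population b (count 1, multiplicity
#' `Mb`), with unitary synaptic efficiency `U`.
#'
#' @param R Ratio of population-a to population-b input neuron counts
#'   (positive real; treated as continuous).
#' @param Ma,Mb Synaptic contacts per input neuron, integers >= 1.
#' @param U Unitary synaptic efficiency, in \[0, 1\].
#' @return An object of class `two_population_model`.
#' @export
two_population_model <- function(R, Ma, Mb, U) {
  check_positive(R, "R")
  Ma <- check_count(Ma, "Ma")
  Mb <- check_count(Mb, "Mb")
  check_probability(U, "U")
  structure(list(R = R, Ma = Ma, Mb = Mb, U = U),
            class = "two_population_model")
}

#' @export
print.two_population_model <- function(x, ...) {
  cat(sprintf(
    "Two-population multiplicity model: R = %g, Ma = %d, Mb = %d, U = %g\n",
    x$R, x$Ma, x$Mb, x$U))
  invisible(x)
}

#' Discrete multiplicity mixture
#'
#' General distribution of synapses-per-connection: each input neuron makes
#' `M[k]` contacts with probability (population fraction) `f[k]`. Generalizes
#' the two-population model, which corresponds to two entries with
#' `f[1]/f[2] = R`.
#'
#' @param M Integer multiplicities >= 1, distinct.
#' @param f Population fractions, nonnegative, summing to 1 (within 1e-9).
#' @return An object of class `multiplicity_mix` with elements `M` and `f`.
#' @examples
#' # mixture calibrated to adult mouse V1 EM reconstructions
#' # (mean synapses per connection ~1.09, ~8% multi-contact)
#' default_multiplicity_mix()
#' @export
multiplicity_mix <- function(M, f) {
  if (length(M) == 0L || length(M) != length(f)) {
    stop_domain("M", "mixture must have >= 1 entry with matching fractions")
  }
  if (any(!is.finite(M)) || any(M < 1) || any(M != round(M))) {
    stop_domain("M", "multiplicities must be integers >= 1")
  }
  if (anyDuplicated(M)) stop_domain("M", "multiplicities must be distinct")
  if (any(!is.finite(f)) || any(f < 0)) {
    stop_domain("f", "fractions must be nonnegative")
  }
  if (abs(sum(f) - 1) > 1e-9) stop_domain("f", "fractions must sum to 1")
  o <- order(M)
  structure(list(M = as.integer(M[o]), f = as.numeric(f[o])),
            class = "multiplicity_mix")
}

#' @rdname multiplicity_mix
#' @export
default_multiplicity_mix <- function() {
  multiplicity_mix(M = c(1L, 2L, 3L), f = c(0.92, 0.067, 0.013))
}

#' Mean synapses per connection of a multiplicity mixture
#' @param mix A [multiplicity_mix()].
#' @export
mean_multiplicity <- function(mix) {
  stopifnot(inherits(mix, "multiplicity_mix"))
  sum(mix$f * mix$M)
}

#' @export
print.multiplicity_mix <- function(x, ...) {
  cat("Multiplicity mixture (synapses per connection):\n")
  print(data.frame(M = x$M, fraction = x$f), row.names = FALSE)
  cat(sprintf("mean multiplicity = %.4f\n", mean_multiplicity(x)))
  invisible(x)
}

new_model_evaluation <- function(pa, pb, IF, SF) {
  ratio <- if (SF == 0) 1 else IF / SF
  structure(list(pa = pa, pb = pb, IF = IF, SF = SF, ratio = ratio),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("IF = %.4f, SF = %.4f, IF/SF = %.4f\n", x$IF, x$SF, x$ratio))
  invisible(x)
}

#' Evaluate the two-population model
#'
#' Computes per-population labeling probabilities `pa`, `pb`, the input
#' fraction `IF = (R pa + pb)/(R + 1)`, the synaptic fraction
#' `SF = (R pa Ma + pb Mb)/(Ma R + Mb)`, and the ratio IF/SF (defined as 1
#' when SF = 0, i.e. U = 0, so sweeps stay finite).
#'
#' @param model A [two_population_model()], or `R` when the individual
#'   parameters are given.
#' @param Ma,Mb,U Optional individual parameters (used when `model` is the
#'   numeric `R`).
#' @return An object of class `model_evaluation` with elements `pa`, `pb`,
#'   `IF`, `SF`, `ratio`.
#' @examples
#' evaluate_model(two_population_model(R = 2, Ma = 1, Mb = 2, U = 0.28))
#' evaluate_model(2, 1, 2, 0.28)$ratio  # ~0.91
#' @export
evaluate_model <- function(model, Ma = NULL, Mb = NULL, U = NULL) {
  if (!inherits(model, "two_population_model")) {
    model <- two_population_model(model, Ma, Mb, U)
  }
  pa <- labeling_probability(model$U, model$Ma)
  pb <- labeling_probability(model$U, model$Mb)
  IF <- (model$R * pa + pb) / (model$R + 1)
  SF <- (model$R * pa * model$Ma + pb * model$Mb) /
    (model$Ma * model$R + model$Mb)
  new_model_evaluation(pa, pb, IF, SF)
}

#' Evaluate a multiplicity mixture
#'
#' Mixture generalization of [evaluate_model()]: with population fractions
#' `f_k` and multiplicities `M_k`, `IF = sum f_k p_k` and
#' `SF = sum f_k M_k p_k / sum f_k M_k` where `p_k = 1 - (1-U)^M_k`.
#' Reduces exactly to the two-population form when the mixture has two
#' entries with `f1/f2 = R`.
#'
#' @param mix A [multiplicity_mix()].
#' @param U Unitary synaptic efficiency.
#' @return An object of class `model_evaluation` (`pa`, `pb` are `NA` unless
#'   the mixture has exactly two entries).
#' @export
evaluate_mixture <- function(mix, U) {
  if (!inherits(mix, "multiplicity_mix")) {
    stop_domain("mix", "must be a multiplicity_mix")
  }
  check_probability(U, "U")
  p <- labeling_probability(U, mix$M)
  IF <- sum(mix$f * p)
  SF <- sum(mix$f * mix$M * p) / sum(mix$f * mix$M)
  if (length(mix$M) == 2L) {
    new_model_evaluation(p[1L], p[2L], IF, SF)
  } else {
    new_model_evaluation(NA_real_, NA_real_, IF, SF)
  }
}

#' Solve for the unitary synaptic efficiency giving a target SF
#'
#' Inverts the SF formula of the two-population model for U by bisection on
#' \[0, 1\] (SF is strictly increasing in U), to absolute tolerance `tol`.
#'
#' @param SF_target Target synaptic fraction, strictly in (0, 1).
#' @param R,Ma,Mb Model parameters as in [two_population_model()].
#' @param tol Absolute tolerance on U (default 1e-9).
#' @return The unitary synaptic efficiency U.
#' @examples
#' solve_unitary_efficiency(0.4, R = 10, Ma = 1, Mb = 2)  # ~0.36
#' @export
solve_unitary_efficiency <- function(SF_target, R, Ma, Mb, tol = 1e-9) {
  if (!is.numeric(SF_target) || length(SF_target) != 1L ||
      !is.finite(SF_target) || SF_target <= 0 || SF_target >= 1) {
    stop_domain("SF_target", "must be strictly between 0 and 1")
  }
  check_positive(R, "R")
  Ma <- check_count(Ma, "Ma")
  Mb <- check_count(Mb, "Mb")
  sf_at <- function(U) evaluate_model(R, Ma, Mb, U)$SF
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sf_at(mid) < SF_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Minimize IF/SF over the population ratio R
#'
#' Finds the ratio R in `[R_min, R_max]` minimizing IF/SF for fixed
#' (U, Ma, Mb). The minimum can be a shallow interior dip, so a coarse
#' log-spaced grid scan (`n_grid` points, >= 200) brackets it before
#' golden-section refinement to relative tolerance `rel_tol`.
#'
#' @param U Unitary synaptic efficiency.
#' @param Ma,Mb Multiplicities.
#' @param R_min,R_max Search bracket, `0 < R_min < R_max`.
#' @param n_grid Grid points for the coarse scan (default 256).
#' @param rel_tol Relative tolerance on R (default 1e-6).
#' @return List with `R_star` (argmin) and `ratio_star` (minimum IF/SF).
#' @examples
#' minimize_if_sf_over_R(U = 0.22, Ma = 1, Mb = 3,
#'                       R_min = 0.01, R_max = 100)$ratio_star  # ~0.8
#' @export
minimize_if_sf_over_R <- function(U, Ma, Mb, R_min, R_max,
                                  n_grid = 256L, rel_tol = 1e-6) {
  check_probability(U, "U")
  Ma <- check_count(Ma, "Ma")
  Mb <- check_count(Mb, "Mb")
  check_positive(R_min, "R_min")
  check_positive(R_max, "R_max")
  if (R_min >= R_max) stop_domain("R_min", "bracket requires R_min < R_max")
  n_grid <- max(200L, check_count(n_grid, "n_grid", min = 3L))

  ratio_at <- function(R) evaluate_model(R, Ma, Mb, U)$ratio
  grid <- exp(seq(log(R_min), log(R_max), length.out = n_grid))
  vals <- vapply(grid, ratio_at, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  if (lo == hi) {
    return(list(R_star = grid[i], ratio_star = vals[i]))
  }
  opt <- optimize(ratio_at, lower = lo, upper = hi,
                  tol = rel_tol * max(1, hi))
  # grid endpoint may beat the local refinement when the min sits on the edge
  if (vals[i] < opt$objective) {
    list(R_star = grid[i], ratio_star = vals[i])
  } else {
    list(R_star = opt$minimum, ratio_star = opt$objective)
  }
}

#' Parameter sweep of the two-population model
#'
#' Evaluates the model pointwise over the Cartesian grid of `U_values` and
#' `R_grid` at fixed (Ma, Mb), in deterministic order (U outer, R inner).
#'
#' @param U_values Unitary efficiencies to sweep.
#' @param R_grid Population ratios to sweep.
#' @param Ma,Mb Multiplicities.
#' @return A data.frame with columns `U, R, Ma, Mb, SF, IF, ratio`, one row
#'   per (U, R) pair.
#' @export
sweep_curves <- function(U_values, R_grid, Ma, Mb) {
  if (length(U_values) == 0L || length(R_grid) == 0L) {
    stop_domain("U_values", "sweep grids must be nonempty")
  }
  Ma <- check_count(Ma, "Ma")
  Mb <- check_count(Mb, "Mb")
  rows <- expand.grid(R = as.numeric(R_grid), U = as.numeric(U_values),
                      KEEP.OUT.ATTRS = FALSE)[, c("U", "R")]
  ev <- mapply(function(u, r) {
    e <- evaluate_model(r, Ma, Mb, u)
    c(e$SF, e$IF, e$ratio)
  }, rows$U, rows$R)
  data.frame(U = rows$U, R = rows$R, Ma = Ma, Mb = Mb,
             SF = ev[1L, ], IF = ev[2L, ], ratio = ev[3L, ])
}

#' Write a sweep table as CSV
#'
#' Header `U,R,Ma,Mb,SF,IF,ratio`, floating-point values at 6 significant
#' digits.
#'
#' @param sweep Result of [sweep_curves()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(is.data.frame(sweep),
            identical(names(sweep), c("U", "R", "Ma", "Mb", "SF", "IF", "ratio")))
  out <- sweep
  for (col in c("U", "R", "SF", "IF", "ratio")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
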