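# Stochastic simulator of rabies spread over an explicit starter/input
# contact graph. Serves as the brute-force oracle for the closed-form model
# and the common-input correction: each individual synaptic contact is
# crossed independently with probability U; an input neuron is labeled iff
# at least one of its contacts onto ANY starter is crossed; every contact
# from a labeled input neuron then carries presynaptic label, including
# contacts never crossed themselves. The latter is exactly the mechanism
# behind shared-input inflation of SF.

#' Explicit starter/input contact graph
#'
#' @param starters data.frame with columns `id, x_um, y_um, z_um` (starter
#'   soma positions).
#' @param contacts data.frame with columns `input_id, starter_id,
#'   n_contacts` (one row per connection; `n_contacts >= 1`; the
#'   `(input_id, starter_id)` pairs must be unique and every `starter_id`
#'   must appear in `starters`).
#' @param inputs Optional vector of input ids; defaults to the ids present
#'   in `contacts`. Every input must appear in at least one contact record.
#' @param starter_inputs Optional vector of input ids that are themselves
#'   starter cells (used to flag background label from starter-to-starter
#'   connections); default none.
#' @return An object of class `synthetic_circuit`.
#' @export
synthetic_circuit <- function(starters, contacts, inputs = NULL,
                              starter_inputs = character()) {
  stopifnot(is.data.frame(starters), is.data.frame(contacts))
  need_s <- c("id", "x_um", "y_um", "z_um")
  if (!all(need_s %in% names(starters))) {
    stop_domain("starters", sprintf("needs columns %s", paste(need_s, collapse = ",")))
  }
  need_c <- c("input_id", "starter_id", "n_contacts")
  if (!all(need_c %in% names(contacts))) {
    stop_domain("contacts", sprintf("needs columns %s", paste(need_c, collapse = ",")))
  }
  if (anyDuplicated(starters$id)) stop_domain("starters", "ids must be unique")
  if (nrow(contacts) > 0L) {
    if (any(!is.finite(contacts$n_contacts)) || any(contacts$n_contacts < 1) ||
        any(contacts$n_contacts != round(contacts$n_contacts))) {
      stop_domain("n_contacts", "must be integers >= 1")
    }
    if (anyDuplicated(contacts[, c("input_id", "starter_id")])) {
      stop_domain("contacts", "(input_id, starter_id) pairs must be unique")
    }
    if (!all(contacts$starter_id %in% starters$id)) {
      stop_domain("contacts", "every starter_id must appear in starters")
    }
  }
  contact_inputs <- unique(contacts$input_id)
  if (is.null(inputs)) {
    inputs <- contact_inputs
  } else if (!all(inputs %in% contact_inputs) ||
             !all(contact_inputs %in% inputs)) {
    stop_domain("inputs", "every input must appear in >= 1 contact record")
  }
  contacts$input_id <- as.character(contacts$input_id)
  contacts$starter_id <- as.character(contacts$starter_id)
  contacts$n_contacts <- as.integer(contacts$n_contacts)
  starters$id <- as.character(starters$id)
  structure(list(starters = starters,
                 inputs = as.character(inputs),
                 contacts = contacts,
                 starter_inputs = as.character(starter_inputs)),
            class = "synthetic_circuit")
}

#' @export
print.synthetic_circuit <- function(x, ...) {
  cat(sprintf(
    "Synthetic circuit: %d starter(s), %d input neuron(s), %d connection(s), %d synaptic contact(s)\n",
    nrow(x$starters), length(x$inputs), nrow(x$contacts),
    sum(x$contacts$n_contacts)))
  invisible(x)
}

#' Simulate one rabies tracing experiment on a circuit
#'
#' Crosses each individual synaptic contact independently with probability
#' `U`; labels an input neuron iff any of its contacts (onto any starter)
#' is crossed; counts a contact as presynaptically labeled iff its input
#' neuron is labeled. Deterministic given `seed`. Per-contact uniform draws
#' are compared to `U`, so with a common seed the labeled set at a larger U
#' is a superset of the labeled set at a smaller U (monotone coupling).
#'
#' @param circuit A [synthetic_circuit()].
#' @param U Unitary synaptic efficiency, in \[0, 1\].
#' @param seed Integer seed.
#' @param u_map Optional named numeric vector overriding U per connection
#'   (names `input_id:starter_id`); hook for spatially varying efficiency.
#' @return An object of class `spread_outcome`: `labeled_inputs`,
#'   `per_starter` (data.frame `starter_id, S_star, S, sf`), `if_overall`,
#'   `convergence_index`, `U`, `seed`.
#' @export
simulate_spread <- function(circuit, U, seed, u_map = NULL) {
  stopifnot(inherits(circuit, "synthetic_circuit"))
  check_probability(U, "U")
  ct <- circuit$contacts
  n_conn <- nrow(ct)
  u_conn <- rep(U, n_conn)
  if (!is.null(u_map)) {
    key <- paste(ct$input_id, ct$starter_id, sep = ":")
    hit <- match(key, names(u_map))
    u_conn[!is.na(hit)] <- u_map[hit[!is.na(hit)]]
  }
  total_contacts <- sum(ct$n_contacts)
  crossed_any <- if (n_conn == 0L) {
    logical(0)
  } else {
    with_seed(seed, {
      u <- runif(total_contacts)
      conn_of <- rep.int(seq_len(n_conn), ct$n_contacts)
      crossed <- u < u_conn[conn_of]
      rowsum(as.integer(crossed), conn_of)[, 1L] > 0L
    })
  }
  labeled_inputs <- unique(ct$input_id[crossed_any])
  input_labeled <- ct$input_id %in% labeled_inputs

  s_total <- tapply(ct$n_contacts, ct$starter_id, sum)
  s_star <- tapply(ifelse(input_labeled, ct$n_contacts, 0L),
                   ct$starter_id, sum)
  ids <- circuit$starters$id
  S <- as.integer(s_total[ids]); S[is.na(S)] <- 0L
  Sst <- as.integer(s_star[ids]); Sst[is.na(Sst)] <- 0L
  per_starter <- data.frame(starter_id = ids, S_star = Sst, S = S,
                            sf = ifelse(S > 0, Sst / S, NA_real_))
  structure(list(labeled_inputs = labeled_inputs,
                 per_starter = per_starter,
                 if_overall = if (length(circuit$inputs) > 0)
                   length(labeled_inputs) / length(circuit$inputs) else NA_real_,
                 convergence_index = length(labeled_inputs) / nrow(circuit$starters),
                 U = U, seed = seed),
            class = "spread_outcome")
}

#' @export
print.spread_outcome <- function(x, ...) {
  cat(sprintf(
    "Spread outcome (U = %g, seed = %d): IF = %.4f, CI = %.2f labeled inputs/starter\n",
    x$U, x$seed, x$if_overall, x$convergence_index))
  print(x$per_starter, row.names = FALSE)
  invisible(x)
}

#' Replicate the spread simulation and summarize
#'
#' Runs [simulate_spread()] `n_reps` times with independent per-replicate
#' seeds derived from `seed`, and reports per-starter mean/SE of SF, the
#' mean/SE of IF, and the mean convergence index. SE is the standard
#' deviation across replicates divided by `sqrt(n_reps)`.
#'
#' @param circuit A [synthetic_circuit()].
#' @param U Unitary synaptic efficiency.
#' @param n_reps Number of replicates, >= 1.
#' @param seed Root integer seed.
#' @return List with `per_starter` (data.frame `starter_id, sf_mean, sf_se`),
#'   `sf_mean`, `sf_se` (grand mean over starters), `if_mean`, `if_se`,
#'   `ci_mean`, `n_reps`, `seed`.
#' @export
estimate_metrics <- function(circuit, U, n_reps, seed) {
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  seeds <- derive_seeds(seed, n_reps)
  sf_mat <- matrix(NA_real_, nrow = n_reps, ncol = nrow(circuit$starters))
  if_vec <- numeric(n_reps)
  ci_vec <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    out <- simulate_spread(circuit, U, seeds[i])
    sf_mat[i, ] <- out$per_starter$sf
    if_vec[i] <- out$if_overall
    ci_vec[i] <- out$convergence_index
  }
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  per_starter <- data.frame(
    starter_id = circuit$starters$id,
    sf_mean = colMeans(sf_mat),
    sf_se = apply(sf_mat, 2L, se))
  grand_sf <- rowMeans(sf_mat)
  list(per_starter = per_starter,
       sf_mean = mean(grand_sf), sf_se = se(grand_sf),
       if_mean = mean(if_vec), if_se = se(if_vec),
       ci_mean = mean(ci_vec),
       n_reps = n_reps, seed = seed)
}

# I/O -------------------------------------------------------------------------

#' Write / read a circuit as plain-text files
#'
#' The contact graph is a TSV edge list `input_id<TAB>starter_id<TAB>n_contacts`
#' and starter positions a CSV `id,x_um,y_um,z_um`.
#'
#' @param circuit A [synthetic_circuit()].
#' @param edge_tsv,starter_csv File paths.
#' @return `write_circuit()`: `edge_tsv` invisibly; `read_circuit()`: a
#'   [synthetic_circuit()].
#' @export
write_circuit <- function(circuit, edge_tsv, starter_csv) {
  stopifnot(inherits(circuit, "synthetic_circuit"))
  write.table(circuit$contacts[, c("input_id", "starter_id", "n_contacts")],
              edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(circuit$starters[, c("id", "x_um", "y_um", "z_um")],
            starter_csv, row.names = FALSE, quote = FALSE)
  invisible(edge_tsv)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(edge_tsv, starter_csv) {
  contacts <- read.delim(edge_tsv, colClasses = c("character", "character",
                                                  "integer"))
  starters <- read.csv(starter_csv, colClasses = c("character", "numeric",
                                                   "numeric", "numeric"))
  synthetic_circuit(starters, contacts)
}

#' Write a spread outcome summary as JSON
#'
#' @param outcome A `spread_outcome` or the result of [estimate_metrics()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_outcome_json <- function(outcome, path) {
  if (inherits(outcome, "spread_outcome")) {
    payload <- list(U = outcome$U, seed = outcome$seed,
                    n_labeled_inputs = length(outcome$labeled_inputs),
                    if_overall = outcome$if_overall,
                    convergence_index = outcome$convergence_index,
                    per_starter = outcome$per_starter)
  } else {
    payload <- outcome
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
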