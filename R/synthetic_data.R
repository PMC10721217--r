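# Generators producing circuits and measurement datasets with the
# statistical structure the analysis assumes: spatially embedded starter
# cells with distance-dependent shared input, a multiplicity distribution
# dominated by single contacts, and per-neuron puncta-colocalization count
# tables calibrated to the measured group means/SEMs. Pure functions of
# (spec, seed): identical arguments give bit-identical output.

#' Specification of a synthetic circuit
#'
#' @param n_starters Number of starter cells, >= 1.
#' @param inputs_per_starter Private input neurons per starter, >= 1.
#' @param multiplicity_mix A [multiplicity_mix()]; default
#'   [default_multiplicity_mix()].
#' @param sharing_profile List of [distance_bin()] objects giving the
#'   fraction of a starter's inputs rewired to also contact a neighboring
#'   starter at that distance; `NULL` for isolated starters.
#' @param starter_positions Optional data.frame `id,x_um,y_um,z_um`; if
#'   omitted, starters are placed uniformly at random in a cube of side
#'   `field_um` (seeded).
#' @param field_um Side of the placement field in um (default 200, the
#'   extent over which sharing is non-negligible).
#' @param seed Integer seed.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_starters, inputs_per_starter,
                         multiplicity_mix = default_multiplicity_mix(),
                         sharing_profile = NULL,
                         starter_positions = NULL,
                         field_um = 200, seed = 1L) {
  n_starters <- check_count(n_starters, "n_starters")
  inputs_per_starter <- check_count(inputs_per_starter, "inputs_per_starter")
  stopifnot(inherits(multiplicity_mix, "multiplicity_mix"))
  if (!is.null(sharing_profile)) validate_profile(sharing_profile)
  if (!is.null(starter_positions)) {
    need <- c("id", "x_um", "y_um", "z_um")
    if (!is.data.frame(starter_positions) ||
        !all(need %in% names(starter_positions)) ||
        nrow(starter_positions) != n_starters) {
      stop("starter_positions must be a data.frame id,x_um,y_um,z_um with one row per starter",
           call. = FALSE)
    }
  }
  check_positive(field_um, "field_um")
  structure(list(n_starters = n_starters,
                 inputs_per_starter = inputs_per_starter,
                 multiplicity_mix = multiplicity_mix,
                 sharing_profile = sharing_profile,
                 starter_positions = starter_positions,
                 field_um = field_um,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "circuit_spec")
}

shared_fraction_at <- function(profile, d) {
  if (is.null(profile)) return(0)
  for (bin in profile) {
    if (d >= bin$r_min && d < bin$r_max) return(bin$shared_fraction)
  }
  0
}

#' Generate a synthetic starter/input circuit
#'
#' Each starter receives `inputs_per_starter` private connections with
#' multiplicities drawn from the mixture. Then, for each ordered starter
#' pair (i, j) at distance d, a fraction `s(d)` of i's private inputs
#' (piecewise-constant from the sharing profile) is rewired to also contact
#' j, with a fresh multiplicity drawn from the mixture. Deterministic given
#' the spec's seed.
#'
#' @param spec A [circuit_spec()].
#' @return A [synthetic_circuit()].
#' @export
generate_circuit <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  mix <- spec$multiplicity_mix
  with_seed(spec$seed, {
    starters <- spec$starter_positions
    if (is.null(starters)) {
      starters <- data.frame(
        id = sprintf("s%d", seq_len(spec$n_starters)),
        x_um = runif(spec$n_starters, 0, spec$field_um),
        y_um = runif(spec$n_starters, 0, spec$field_um),
        z_um = runif(spec$n_starters, 0, spec$field_um))
    }
    starters$id <- as.character(starters$id)

    n_private <- spec$n_starters * spec$inputs_per_starter
    input_id <- sprintf("i%d", seq_len(n_private))
    owner <- rep(starters$id, each = spec$inputs_per_starter)
    m <- sample(mix$M, n_private, replace = TRUE, prob = mix$f)
    contacts <- data.frame(input_id = input_id, starter_id = owner,
                           n_contacts = as.integer(m))

    if (!is.null(spec$sharing_profile) && spec$n_starters > 1L) {
      extra <- vector("list", spec$n_starters * (spec$n_starters - 1L))
      k <- 0L
      pos <- as.matrix(starters[, c("x_um", "y_um", "z_um")])
      for (i in seq_len(spec$n_starters)) {
        own_idx <- which(owner == starters$id[i])
        for (j in seq_len(spec$n_starters)) {
          if (i == j) next
          d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
          s <- shared_fraction_at(spec$sharing_profile, d)
          if (s <= 0) next
          shared <- own_idx[runif(length(own_idx)) < s]
          if (length(shared) == 0L) next
          k <- k + 1L
          extra[[k]] <- data.frame(
            input_id = input_id[shared],
            starter_id = starters$id[j],
            n_contacts = as.integer(sample(mix$M, length(shared),
                                           replace = TRUE, prob = mix$f)))
        }
      }
      if (k > 0L) {
        extra <- do.call(rbind, extra[seq_len(k)])
        # a pair can only be duplicated if an input was rewired to j twice,
        # impossible here, but keep the container invariant defensive
        contacts <- rbind(contacts, extra)
        contacts <- contacts[!duplicated(contacts[, c("input_id", "starter_id")]), ]
      }
    }
    synthetic_circuit(starters, contacts)
  })
}

# Puncta tables ----------------------------------------------------------------

#' Specification of synthetic puncta-colocalization count tables
#'
#' Emulates per-dendritic-segment counting of PSD-95-labeled postsynaptic
#' densities and apposed rabies-labeled presynaptic puncta. Per neuron, a
#' true apposed probability is drawn from a Beta distribution with the
#' group's mean and `concentration` (beta-binomial over-dispersion, so the
#' between-neuron SEM is matchable, not just the mean); per segment,
#' `n_psd ~ Poisson(psd_per_segment_mean)` and
#' `n_apposed ~ Binomial(n_psd, p_neuron)`. `concentration = Inf` gives pure
#' binomial counts.
#'
#' @param groups data.frame with columns `label, n_neurons, n_animals,
#'   segments_per_neuron, psd_per_segment_mean, true_apposed_fraction,
#'   concentration`.
#' @param seed Integer seed.
#' @return An object of class `puncta_spec`.
#' @export
puncta_spec <- function(groups, seed = 1L) {
  need <- c("label", "n_neurons", "n_animals", "segments_per_neuron",
            "psd_per_segment_mean", "true_apposed_fraction", "concentration")
  if (!is.data.frame(groups) || !all(need %in% names(groups)) ||
      nrow(groups) == 0L) {
    stop(sprintf("groups must be a data.frame with columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  if (any(groups$true_apposed_fraction < 0 | groups$true_apposed_fraction > 1)) {
    stop_domain("true_apposed_fraction", "must be in [0, 1]")
  }
  if (any(groups$n_neurons < 1 | groups$n_animals < 1 |
          groups$segments_per_neuron < 1 | groups$psd_per_segment_mean <= 0)) {
    stop_domain("groups", "counts must be >= 1 and psd mean > 0")
  }
  structure(list(groups = groups, seed = check_count(seed, "seed", min = 0L)),
            class = "puncta_spec")
}

#' Default puncta spec: L4 excitatory starters with and without oG
#'
#' Two groups matching the measured design: 9 neurons across 3 mice with
#' glycoprotein trans-complementation (true colocalization 50.61%) and 5
#' neurons across 2 mice without oG (background 8.86%). Beta concentrations
#' (17 and 49) are calibrated so the between-neuron spread reproduces the
#' printed SEMs (3.92% and 1.79%); 4 segments of ~80 PSDs per neuron
#' reflect typical Airyscan dendritic fields.
#'
#' @param seed Integer seed.
#' @return A [puncta_spec()].
#' @export
default_puncta_spec <- function(seed = 1L) {
  puncta_spec(data.frame(
    label = c("oG", "no_oG"),
    n_neurons = c(9L, 5L),
    n_animals = c(3L, 2L),
    segments_per_neuron = c(4L, 4L),
    psd_per_segment_mean = c(80, 80),
    true_apposed_fraction = c(0.5061, 0.0886),
    concentration = c(17, 49)), seed = seed)
}

#' Generate a per-segment puncta count table
#'
#' @param spec A [puncta_spec()].
#' @return A data.frame of class `puncta_table` with columns
#'   `neuron_id, animal_id, group, compartment, segment_id, n_psd,
#'   n_apposed`.
#' @export
generate_puncta_table <- function(spec) {
  stopifnot(inherits(spec, "puncta_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$groups)), function(g) {
      grp <- spec$groups[g, ]
      p_neuron <- if (is.finite(grp$concentration)) {
        if (grp$true_apposed_fraction %in% c(0, 1)) {
          rep(grp$true_apposed_fraction, grp$n_neurons)
        } else {
          rbeta(grp$n_neurons,
                grp$true_apposed_fraction * grp$concentration,
                (1 - grp$true_apposed_fraction) * grp$concentration)
        }
      } else {
        rep(grp$true_apposed_fraction, grp$n_neurons)
      }
      animal <- rep_len(seq_len(grp$n_animals), grp$n_neurons)
      do.call(rbind, lapply(seq_len(grp$n_neurons), function(i) {
        n_seg <- grp$segments_per_neuron
        n_psd <- rpois(n_seg, grp$psd_per_segment_mean)
        n_app <- rbinom(n_seg, n_psd, p_neuron[i])
        data.frame(
          neuron_id = sprintf("%s_n%d", grp$label, i),
          animal_id = sprintf("%s_m%d", grp$label, animal[i]),
          group = grp$label,
          compartment = rep_len(c("proximal", "distal"), n_seg),
          segment_id = seq_len(n_seg),
          n_psd = n_psd,
          n_apposed = n_app)
      }))
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("puncta_table", "data.frame")
    tab
  })
}

#' Generate synthetic puncta point sets along a dendrite
#'
#' Places PSD points along a straight dendritic segment (Poisson positions
#' at `psd_density_per_um`); for a fraction `apposed_fraction` of them, a
#' presynaptic partner point is placed uniformly within the anisotropic
#' jitter ellipsoid (semi-axes `jitter_xy_um` laterally, `jitter_z_um`
#' axially). Optional distractor presynaptic points are placed on a parallel
#' line offset by `distractor_offset_um` laterally, i.e. outside any
#' tolerance smaller than the offset.
#'
#' @param segment_length_um Dendrite length (um), > 0.
#' @param psd_density_per_um Expected PSDs per um, > 0.
#' @param apposed_fraction Fraction of PSDs with a true presynaptic partner.
#' @param jitter_xy_um,jitter_z_um Partner displacement bounds (um), >= 0.
#' @param seed Integer seed.
#' @param n_distractors Number of unpaired presynaptic points (default 0).
#' @param distractor_offset_um Lateral offset of distractors (default 2 um).
#' @return List with data.frames `psd` and `syn` (`x_um,y_um,z_um,channel`)
#'   and `matching`: data.frame `psd_idx, syn_idx` of planted pairs.
#' @export
generate_puncta_points <- function(segment_length_um, psd_density_per_um,
                                   apposed_fraction, jitter_xy_um,
                                   jitter_z_um, seed,
                                   n_distractors = 0L,
                                   distractor_offset_um = 2) {
  check_positive(segment_length_um, "segment_length_um")
  check_positive(psd_density_per_um, "psd_density_per_um")
  check_probability(apposed_fraction, "apposed_fraction")
  if (jitter_xy_um < 0 || jitter_z_um < 0) {
    stop_domain("jitter", "jitters must be >= 0")
  }
  n_distractors <- check_count(n_distractors, "n_distractors", min = 0L)
  with_seed(seed, {
    n_psd <- rpois(1L, segment_length_um * psd_density_per_um)
    psd <- data.frame(x_um = sort(runif(n_psd, 0, segment_length_um)),
                      y_um = 0, z_um = 0, channel = "psd95")
    paired <- which(runif(n_psd) < apposed_fraction)
    syn <- NULL
    if (length(paired) > 0L) {
      # uniform draw inside the jitter ellipsoid by rejection
      offs <- t(vapply(seq_along(paired), function(i) {
        repeat {
          v <- runif(3, -1, 1)
          if (sum(v^2) <= 1) return(v * c(jitter_xy_um, jitter_xy_um,
                                          jitter_z_um))
        }
      }, numeric(3)))
      syn <- data.frame(x_um = psd$x_um[paired] + offs[, 1],
                        y_um = psd$y_um[paired] + offs[, 2],
                        z_um = psd$z_um[paired] + offs[, 3],
                        channel = "synphrfp")
    }
    if (n_distractors > 0L) {
      dis <- data.frame(x_um = runif(n_distractors, 0, segment_length_um),
                        y_um = distractor_offset_um, z_um = 0,
                        channel = "synphrfp")
      syn <- if (is.null(syn)) dis else rbind(syn, dis)
    }
    if (is.null(syn)) {
      syn <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        z_um = numeric(0), channel = character(0))
    }
    list(psd = psd, syn = syn,
         matching = data.frame(psd_idx = paired,
                               syn_idx = seq_along(paired)))
  })
}

# I/O -------------------------------------------------------------------------

#' Write / read a puncta table as CSV
#'
#' Columns `neuron_id,animal_id,group,compartment,segment_id,n_psd,n_apposed`.
#'
#' @param table A `puncta_table` data.frame.
#' @param path CSV path.
#' @return `write_puncta_csv()`: `path` invisibly; `read_puncta_csv()`: a
#'   `puncta_table`.
#' @export
write_puncta_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_puncta_csv
#' @export
read_puncta_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("neuron_id", "animal_id", "group", "compartment", "segment_id",
            "n_psd", "n_apposed")
  if (!all(need %in% names(tab))) {
    stop(sprintf("puncta CSV must have columns %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  if (any(tab$n_apposed > tab$n_psd) || any(tab$n_apposed < 0)) {
    stop("puncta table requires 0 <= n_apposed <= n_psd", call. = FALSE)
  }
  class(tab) <- c("puncta_table", "data.frame")
  tab
}

#' Write a point set as CSV (`x_um,y_um,z_um,channel`)
#' @param points data.frame with those columns.
#' @param path CSV path.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(is.data.frame(points),
            all(c("x_um", "y_um", "z_um", "channel") %in% names(points)))
  write.csv(points[, c("x_um", "y_um", "z_um", "channel")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
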