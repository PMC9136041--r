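# Seeded synthetic cohort generator.  Emulates the study design the
# pipeline assumes: four syndrome groups (IPBS, PQD, PQS, PST) of
# 64/64/26/10 serum samples, 800 wide-targeted metabolites in 17
# primary / 43 secondary classes, log-normal peak-area intensities,
# clinical covariates drawn around the cohort's group summaries, and
# configurable group-specific spiked markers with a planted pathway so
# every downstream stage has a testable positive control.

# Group-level covariate parameters of the emulated cohort (means/sds
# and category counts per syndrome group).
.cohort_covariates <- list(
  IPBS = list(n = 64, age = c(62.11, 7.32), weight = c(66.66, 9.76),
              male = 48, hypertension = 43, diabetes = 18,
              fasting_glucose = c(6.20, 1.92), tg = c(1.51, 0.76),
              tc = c(4.03, 1.13), ldl_c = c(2.23, 0.97)),
  PQD = list(n = 64, age = c(61.27, 8.26), weight = c(70.84, 13.76),
             male = 36, hypertension = 48, diabetes = 16,
             fasting_glucose = c(6.29, 1.72), tg = c(1.78, 0.99),
             tc = c(4.19, 1.03), ldl_c = c(2.41, 0.87)),
  PQS = list(n = 26, age = c(59.31, 9.19), weight = c(72.86, 10.18),
             male = 23, hypertension = 17, diabetes = 7,
             fasting_glucose = c(6.38, 2.04), tg = c(1.77, 1.09),
             tc = c(3.91, 0.94), ldl_c = c(2.25, 0.81)),
  PST = list(n = 10, age = c(59.60, 9.61), weight = c(67.55, 8.54),
             male = 8, hypertension = 5, diabetes = 3,
             fasting_glucose = c(6.39, 1.55), tg = c(1.74, 0.89),
             tc = c(3.91, 2.03), ldl_c = c(2.43, 2.12))
)

.primary_classes <- c(
  "amino acids and their metabolites", "glycerol phospholipids",
  "organic acids and their derivatives", "fatty acyls",
  "benzene and its derivatives", "nucleotides and their metabolites",
  "carbohydrates and their metabolites", "bile acids", "sphingolipids",
  "glycerolipids", "sterols and their derivatives", "amines",
  "vitamins and cofactors", "alkaloids", "small peptides",
  "hormones and related compounds", "heterocyclic compounds")

# A handful of marker metabolites get recognizable names; the first
# three are the default spike targets.
.named_markers <- c("anserine", "cytidine 5'-diphosphocholine",
                    "7,8-dihydro-L-biopterin", "canrenone",
                    "D-mannosamine", "oxypurinol")

#' Spiked marker specification
#'
#' @param metabolite_id Metabolite elevated (or depressed) in one group.
#' @param elevated_in Syndrome label whose group mean is shifted.
#' @param log2_effect Target log2 fold change of that group versus all
#'   others; a negative value depresses the group (i.e. the metabolite
#'   is relatively elevated in the remaining groups).
#' @return A `spike_spec` list.
#' @export
spike_spec <- function(metabolite_id, elevated_in, log2_effect) {
  if (!(elevated_in %in% SYNDROME_LEVELS)) {
    stop("elevated_in must be one of ", paste(SYNDROME_LEVELS, collapse = ", "))
  }
  stopifnot(is.numeric(log2_effect), length(log2_effect) == 1)
  structure(list(metabolite_id = metabolite_id, elevated_in = elevated_in,
                 log2_effect = log2_effect), class = "spike_spec")
}

#' Default spiked markers
#'
#' One marker per concurrent syndrome: anserine elevated in PST,
#' cytidine 5'-diphosphocholine elevated in PQS, and
#' 7,8-dihydro-L-biopterin depressed in PQD (i.e. relatively higher in
#' IPBS).  The sign of `log2_effect` carries the direction, so either
#' reading of a marker's orientation is a one-line config change.
#'
#' @return List of [spike_spec()] objects.
#' @export
default_spikes <- function() {
  list(spike_spec("anserine", "PST", 2),
       spike_spec("cytidine 5'-diphosphocholine", "PQS", 2),
       spike_spec("7,8-dihydro-L-biopterin", "PQD", -2))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the emulated study design: 164 samples in groups
#' IPBS 64, PQD 64, PQS 26, PST 10, and 800 metabolites in 17 primary /
#' 43 secondary classes.  Intensities are log-normal: each metabolite
#' draws a baseline log2 mean once (`base_log2_mean` +/-
#' `base_log2_spread`), then every sample adds Gaussian log2 noise of
#' sd `sample_log2_sd` and the result is exponentiated, giving strictly
#' positive right-skewed peak areas.  Spikes shift the log2 mean of
#' their target group only.
#'
#' @param group_sizes Named vector of samples per syndrome (subset of
#'   IPBS/PQD/PQS/PST).
#' @param n_metabolites Number of metabolites.
#' @param n_primary_classes,n_secondary_classes Class counts; each
#'   secondary class nests in exactly one primary class, so
#'   `n_secondary_classes >= n_primary_classes`.
#' @param base_log2_mean Mean of the per-metabolite baseline log2
#'   intensity (default 17, i.e. peak areas around 1e5).
#' @param base_log2_spread SD of the baseline across metabolites.
#' @param sample_log2_sd Per-sample log2 noise sd.
#' @param spikes List of [spike_spec()]; default [default_spikes()].
#' @param missing_rate Fraction of cells set missing completely at
#'   random, in `[0, 1)`.
#' @param n_pathways Number of random pathways in the generated map (a
#'   planted pathway holding the spiked markers is added on top).
#' @param pathway_size_range Min/max members per random pathway.
#' @param seed Integer seed; the generator is a pure function of the
#'   config.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(IPBS = 64, PQD = 64, PQS = 26,
                                          PST = 10),
                          n_metabolites = 800,
                          n_primary_classes = 17,
                          n_secondary_classes = 43,
                          base_log2_mean = 17,
                          base_log2_spread = 2.5,
                          sample_log2_sd = 0.8,
                          spikes = default_spikes(),
                          missing_rate = 0,
                          n_pathways = 20,
                          pathway_size_range = c(5, 40),
                          seed = 1L) {
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% SYNDROME_LEVELS)) {
    stop("group_sizes must be named with labels from ",
         paste(SYNDROME_LEVELS, collapse = ", "))
  }
  stopifnot(all(group_sizes > 0), n_metabolites > 0,
            n_primary_classes > 0,
            n_secondary_classes >= n_primary_classes,
            missing_rate >= 0, missing_rate < 1,
            sample_log2_sd > 0, n_pathways >= 0,
            length(pathway_size_range) == 2,
            pathway_size_range[1] >= 1,
            pathway_size_range[2] >= pathway_size_range[1])
  if (n_primary_classes > length(.primary_classes)) {
    stop("at most ", length(.primary_classes), " primary classes supported")
  }
  if (n_secondary_classes > n_metabolites) {
    stop("more secondary classes than metabolites")
  }
  structure(list(group_sizes = group_sizes, n_metabolites = n_metabolites,
                 n_primary_classes = n_primary_classes,
                 n_secondary_classes = n_secondary_classes,
                 base_log2_mean = base_log2_mean,
                 base_log2_spread = base_log2_spread,
                 sample_log2_sd = sample_log2_sd,
                 spikes = spikes, missing_rate = missing_rate,
                 n_pathways = n_pathways,
                 pathway_size_range = pathway_size_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.metabolite_ids <- function(n) {
  ids <- sprintf("M%04d", seq_len(n))
  named <- utils::head(.named_markers, n)
  ids[seq_along(named)] <- named
  ids
}

#' Generate a synthetic cohort
#'
#' Draws an abundance matrix, sample metadata, metabolite annotation
#' and a pathway map from a [cohort_config()].  Identical seeds give
#' bit-identical output; the global RNG state is left untouched.
#'
#' @param config A `cohort_config`.
#' @return A list with elements `abundance` (matrix, samples x
#'   metabolites, `NA` for injected missing cells), `metadata`
#'   (data.frame), `annotation` (data.frame), `pathways` (data.frame
#'   with a `members` list-column; the planted pathway, if any spikes
#'   exist, has id `SP_SPIKED`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- .metabolite_ids(config$n_metabolites)
  for (s in config$spikes) {
    if (!(s$metabolite_id %in% ids)) {
      stop("spike references absent metabolite: ", s$metabolite_id)
    }
    if (!(s$elevated_in %in% names(config$group_sizes))) {
      stop("spike group absent from cohort: ", s$elevated_in)
    }
  }
  .with_seed(config$seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    p <- config$n_metabolites
    sample_ids <- sprintf("S%03d", seq_len(n))

    baseline <- stats::rnorm(p, config$base_log2_mean,
                             config$base_log2_spread)
    log2mat <- matrix(baseline, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, 0, config$sample_log2_sd), n, p)
    for (s in config$spikes) {
      j <- match(s$metabolite_id, ids)
      log2mat[groups == s$elevated_in, j] <-
        log2mat[groups == s$elevated_in, j] + s$log2_effect
    }
    abundance <- 2^log2mat
    dimnames(abundance) <- list(sample_ids, ids)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
      abundance[mask] <- NA_real_
    }

    metadata <- .draw_metadata(sample_ids, groups)
    annotation <- .draw_annotation(ids, config)
    pathways <- .draw_pathways(annotation, config)
    list(abundance = abundance, metadata = metadata,
         annotation = annotation, pathways = pathways)
  })
}

.draw_metadata <- function(sample_ids, groups) {
  rows <- lapply(seq_along(sample_ids), function(i) {
    g <- groups[i]
    pr <- .cohort_covariates[[g]]
    data.frame(
      sample_id = sample_ids[i], syndrome = g,
      age = round(stats::rnorm(1, pr$age[1], pr$age[2]), 1),
      weight = round(stats::rnorm(1, pr$weight[1], pr$weight[2]), 1),
      sex = if (stats::runif(1) < pr$male / pr$n) "male" else "female",
      hypertension = if (stats::runif(1) < pr$hypertension / pr$n) "yes" else "no",
      diabetes = if (stats::runif(1) < pr$diabetes / pr$n) "yes" else "no",
      fasting_glucose = round(abs(stats::rnorm(1, pr$fasting_glucose[1],
                                               pr$fasting_glucose[2])), 2),
      tg = round(abs(stats::rnorm(1, pr$tg[1], pr$tg[2])), 2),
      tc = round(abs(stats::rnorm(1, pr$tc[1], pr$tc[2])), 2),
      ldl_c = round(abs(stats::rnorm(1, pr$ldl_c[1], pr$ldl_c[2])), 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.draw_annotation <- function(ids, config) {
  p <- length(ids)
  np <- config$n_primary_classes
  ns <- config$n_secondary_classes
  primary_names <- .primary_classes[seq_len(np)]
  # nest secondary classes: one per primary first, extras spread round-robin
  sec_primary <- c(seq_len(np), rep(seq_len(np),
                                    length.out = ns - np))
  secondary_names <- sprintf("%s / subclass %d", primary_names[sec_primary],
                             seq_len(ns))
  # skewed class occupancy: a few classes dominate, as in serum panels;
  # the first ns metabolites cover every secondary class exactly once
  wt <- 1 / sqrt(seq_len(ns))
  sec_of <- c(seq_len(ns),
              sample(seq_len(ns), p - ns, replace = TRUE, prob = wt))
  data.frame(metabolite_id = ids,
             primary_class = primary_names[sec_primary[sec_of]],
             secondary_class = secondary_names[sec_of],
             compound_key = sprintf("CK%04d", seq_len(p)),
             stringsAsFactors = FALSE)
}

.draw_pathways <- function(annotation, config) {
  keys <- annotation$compound_key
  sizes <- if (config$n_pathways > 0) {
    sample(seq(config$pathway_size_range[1],
               config$pathway_size_range[2]),
           config$n_pathways, replace = TRUE)
  } else integer()
  sizes <- pmin(sizes, length(keys))
  members <- lapply(sizes, function(k) sort(sample(keys, k), method = "radix"))
  df <- data.frame(pathway_id = sprintf("SP%03d", seq_along(sizes)),
                   pathway_name = sprintf("Synthetic pathway %d",
                                          seq_along(sizes)),
                   stringsAsFactors = FALSE)
  df$members <- members
  spiked_ids <- vapply(config$spikes, `[[`, "", "metabolite_id")
  if (length(spiked_ids)) {
    spike_keys <- annotation$compound_key[
      match(spiked_ids, annotation$metabolite_id)]
    planted <- data.frame(pathway_id = "SP_SPIKED",
                          pathway_name = "Planted spiked-marker pathway",
                          stringsAsFactors = FALSE)
    planted$members <- list(sort(unique(spike_keys), method = "radix"))
    df <- rbind(df, planted)
  }
  rownames(df) <- NULL
  df
}

#' Per-group covariate summary with cross-group tests
#'
#' Summarizes a metadata table the way cohort characteristics tables
#' are reported: per group n, mean +/- sd for continuous covariates and
#' level counts for categorical ones, with a descriptive cross-group
#' P-value (one-way ANOVA for continuous, chi-square for categorical).
#'
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @return An object of class `cohort_summary`: `n` (named group
#'   sizes), `continuous` (variable/group/mean/sd/p_value),
#'   `categorical` (variable/level/group/count/p_value).
#' @export
cohort_summary <- function(metadata) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "syndrome") %in% colnames(metadata)))
  groups <- intersect(SYNDROME_LEVELS, unique(metadata$syndrome))
  if (!length(groups)) stop("no represented syndrome groups")
  n <- vapply(groups, function(g) sum(metadata$syndrome == g), 0L)
  cont <- intersect(METADATA_NUMERIC, colnames(metadata))
  cat_ <- intersect(c("sex", METADATA_YESNO), colnames(metadata))
  continuous <- do.call(rbind, lapply(cont, function(v) {
    x <- metadata[[v]]
    ok <- !is.na(x)
    pv <- tryCatch({
      fit <- stats::aov(x[ok] ~ factor(metadata$syndrome[ok]))
      summary(fit)[[1]][["Pr(>F)"]][1]
    }, error = function(e) NA_real_)
    data.frame(variable = v, group = groups,
               mean = vapply(groups, function(g)
                 mean(x[metadata$syndrome == g], na.rm = TRUE), 0),
               sd = vapply(groups, function(g)
                 stats::sd(x[metadata$syndrome == g], na.rm = TRUE), 0),
               p_value = pv, row.names = NULL, stringsAsFactors = FALSE)
  }))
  categorical <- do.call(rbind, lapply(cat_, function(v) {
    x <- metadata[[v]]
    ok <- !is.na(x)
    tab <- table(x[ok], metadata$syndrome[ok])
    pv <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)$p.value),
      error = function(e) NA_real_)
    grid <- expand.grid(level = rownames(tab), group = colnames(tab),
                        stringsAsFactors = FALSE)
    data.frame(variable = v, level = grid$level, group = grid$group,
               count = as.integer(tab[cbind(grid$level, grid$group)]),
               p_value = pv, row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(n = n, continuous = continuous, categorical = categorical),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort:", sum(x$n), "samples (",
      paste(names(x$n), x$n, sep = " ", collapse = ", "), ")\n")
  if (!is.null(x$continuous) && nrow(x$continuous)) {
    for (v in unique(x$continuous$variable)) {
      rows <- x$continuous[x$continuous$variable == v, ]
      cat(sprintf("  %s: %s  (P = %.2g)\n", v,
                  paste(sprintf("%s %.2f±%.2f", rows$group, rows$mean,
                                rows$sd), collapse = ", "),
                  rows$p_value[1]))
    }
  }
  invisible(x)
}
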