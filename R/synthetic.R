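# Dirichlet-multinomial cohort simulator.
#
# Each sample draws a mixture component (its true community class), a
# composition from that component's Dirichlet base with the class's driver
# taxon boosted, a library size from a lognormal, and counts from a
# multinomial. Amplification failure is modeled as a library size below a
# threshold; such samples are emitted with their low depth and flagged
# downstream, mirroring non-amplifiable specimens in real runs.

#' Configuration for a simulated cohort
#'
#' @param n_samples number of samples.
#' @param n_taxa number of taxa; taxon ids default to `g01`, `g02`, ...
#' @param K number of mixture components (community classes).
#' @param mixing_weights length-`K` simplex of component probabilities.
#' @param dirichlet_base Dirichlet base parameters: scalar, length-`n_taxa`
#'   vector, or `K x n_taxa` matrix of positive reals.
#' @param driver_taxa integer or character vector, one driver taxon per
#'   component (defaults to taxa `1..K`).
#' @param driver_boost multiplier `>= 1` applied to each component's driver
#'   base parameter (scalar or length `K`).
#' @param depth_log_mean lognormal meanlog of library size; scalar or one
#'   value per component (a component with a very low value acts as the
#'   low-biomass class).
#' @param depth_log_sd lognormal sdlog of library size.
#' @param failure_threshold reads below which a sample counts as
#'   non-amplifiable.
#' @param taxon_names optional explicit taxon ids.
#' @param seed integer seed; generation is a pure function of the config.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_samples, n_taxa, K,
                          mixing_weights = rep(1 / K, K),
                          dirichlet_base = 0.1,
                          driver_taxa = seq_len(K),
                          driver_boost = 50,
                          depth_log_mean = log(2e4),
                          depth_log_sd = 0.5,
                          failure_threshold = 0,
                          taxon_names = NULL,
                          seed = 1L) {
  if (K > n_taxa) stop_("K (%d) exceeds n_taxa (%d)", K, n_taxa)
  if (length(mixing_weights) != K || any(mixing_weights < 0) ||
      abs(sum(mixing_weights) - 1) > 1e-12) {
    stop_("mixing_weights must be a length-K simplex (sum 1 within 1e-12)")
  }
  if (is.null(taxon_names)) {
    taxon_names <- sprintf("g%02d", seq_len(n_taxa))
  }
  if (length(taxon_names) != n_taxa) stop_("taxon_names length mismatch")
  if (is.character(driver_taxa)) {
    driver_taxa <- match(driver_taxa, taxon_names)
    if (anyNA(driver_taxa)) stop_("driver taxon not among taxon_names")
  }
  if (length(driver_taxa) != K || anyDuplicated(driver_taxa)) {
    stop_("need exactly one distinct driver taxon per component")
  }
  driver_boost <- rep_len(driver_boost, K)
  if (any(driver_boost < 1)) stop_("driver_boost must be >= 1")
  base <- dirichlet_base
  if (is.matrix(base)) {
    if (!all(dim(base) == c(K, n_taxa))) stop_("dirichlet_base matrix must be K x n_taxa")
  } else {
    base <- matrix(rep_len(base, n_taxa), nrow = K, ncol = n_taxa,
                   byrow = TRUE)
  }
  if (any(base <= 0)) stop_("dirichlet_base must be positive")
  depth_log_mean <- rep_len(depth_log_mean, K)
  structure(list(n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa), K = as.integer(K),
                 mixing_weights = mixing_weights,
                 dirichlet_base = base,
                 driver_taxa = as.integer(driver_taxa),
                 driver_boost = driver_boost,
                 depth_log_mean = depth_log_mean,
                 depth_log_sd = depth_log_sd,
                 failure_threshold = as.integer(failure_threshold),
                 taxon_names = taxon_names,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Component Dirichlet parameters with the driver boosted.
component_alpha <- function(config, k) {
  a <- config$dirichlet_base[k, ]
  a[config$driver_taxa[k]] <- a[config$driver_taxa[k]] * config$driver_boost[k]
  a
}

#' Simulate a cohort count table
#'
#' @param config a [cohort_config()].
#' @return A list: `table` (a [count_table] with taxon ids as their own
#'   genus map), `labels` (integer component per sample, named),
#'   `failed` (logical, library size below `failure_threshold`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    z <- sample.int(config$K, n, replace = TRUE,
                    prob = config$mixing_weights)
    depth <- pmax(1L, as.integer(round(rlnorm(
      n, meanlog = config$depth_log_mean[z], sdlog = config$depth_log_sd))))
    counts <- matrix(0L, n, config$n_taxa,
                     dimnames = list(sprintf("s%03d", seq_len(n)),
                                     config$taxon_names))
    for (i in seq_len(n)) {
      p <- rdirichlet1(component_alpha(config, z[i]))
      counts[i, ] <- as.integer(rmultinom(1, depth[i], p))
    }
    tab <- count_table(counts,
                       taxonomy = setNames(config$taxon_names,
                                           config$taxon_names))
    list(table = tab,
         labels = setNames(z, rownames(counts)),
         failed = setNames(depth < config$failure_threshold,
                           rownames(counts)))
  })
}

#' Simulate paired timepoints with tunable class association
#'
#' Generates two cohorts over the same samples. With probability
#' `association` a sample's timepoint-2 class is the fixed component mapping
#' of its timepoint-1 class; otherwise it is drawn fresh from the
#' timepoint-2 mixing weights. `association = 1` couples the timepoints
#' deterministically, `association = 0` makes them independent (the null of
#' no enterotype carry-over).
#'
#' @param config_t1,config_t2 [cohort_config()]s with equal `n_samples`.
#' @param association probability in \[0, 1\] of keeping the mapped class.
#' @param mapping integer vector of length `config_t1$K` giving the
#'   timepoint-2 component each timepoint-1 component maps to; defaults to
#'   component index modulo `config_t2$K`.
#' @param seed integer seed for the pairing and both cohorts.
#' @return A list with `t1`, `t2` (each as from [simulate_cohort()]).
#' @export
simulate_paired <- function(config_t1, config_t2, association,
                            mapping = NULL, seed = 1L) {
  stopifnot(inherits(config_t1, "cohort_config"),
            inherits(config_t2, "cohort_config"))
  if (config_t1$n_samples != config_t2$n_samples) {
    stop_("timepoints must have the same n_samples")
  }
  if (association < 0 || association > 1) {
    stop_("association must lie in [0, 1]")
  }
  if (is.null(mapping)) {
    mapping <- ((seq_len(config_t1$K) - 1L) %% config_t2$K) + 1L
  }
  if (length(mapping) != config_t1$K ||
      any(mapping < 1 | mapping > config_t2$K)) {
    stop_("mapping must send each t1 component to a t2 component")
  }
  cfg1 <- config_t1; cfg1$seed <- derive_seed(seed, 1)
  t1 <- simulate_cohort(cfg1)
  n <- config_t1$n_samples
  with_seed(derive_seed(seed, 2), {
    keep <- runif(n) < association
    z2 <- ifelse(keep, mapping[t1$labels],
                 sample.int(config_t2$K, n, replace = TRUE,
                            prob = config_t2$mixing_weights))
    depth <- pmax(1L, as.integer(round(rlnorm(
      n, meanlog = config_t2$depth_log_mean[z2],
      sdlog = config_t2$depth_log_sd))))
    counts <- matrix(0L, n, config_t2$n_taxa,
                     dimnames = list(rownames(t1$table$counts),
                                     config_t2$taxon_names))
    for (i in seq_len(n)) {
      p <- rdirichlet1(component_alpha(config_t2, z2[i]))
      counts[i, ] <- as.integer(rmultinom(1, depth[i], p))
    }
    t2 <- list(table = count_table(counts,
                                   taxonomy = setNames(config_t2$taxon_names,
                                                       config_t2$taxon_names)),
               labels = setNames(as.integer(z2), rownames(counts)),
               failed = setNames(depth < config_t2$failure_threshold,
                                 rownames(counts)))
    list(t1 = t1, t2 = t2, mapping = mapping)
  })
}

#' Simulate a random rooted tree over a taxon set
#'
#' Random binary topology with exponential branch lengths; leaves are the
#' given taxon ids. Deterministic per seed.
#'
#' @param taxon_ids character vector of at least two taxon ids.
#' @param seed integer seed.
#' @param rate rate of the exponential branch-length distribution.
#' @return A rooted `phylo` tree.
#' @export
simulate_tree <- function(taxon_ids, seed = 1L, rate = 1) {
  if (length(taxon_ids) < 2) stop_("need at least 2 taxa for a tree")
  if (anyDuplicated(taxon_ids)) stop_("duplicate taxon ids")
  with_seed(seed, {
    tr <- ape::rtree(length(taxon_ids), rooted = TRUE,
                     br = function(n) rexp(n, rate = rate))
    tr$tip.label <- taxon_ids[as.integer(sub("^t", "", tr$tip.label))]
    validate_tree(tr)
  })
}

#' Simulate covariates conditional on community classes
#'
#' Draws metadata columns whose distribution may shift with the sample's
#' class, for exercising the univariate association screen. A zero effect
#' (equal means / equal level probabilities) makes the covariate independent
#' of the class.
#'
#' @param labels integer class per sample (named by sample id).
#' @param effects named list; each element is either
#'   `list(type = "continuous", means = <per-class>, sd = <shared>)` or
#'   `list(type = "categorical", levels = <chr>, probs = <class x level matrix>)`.
#' @param seed integer seed.
#' @return A `data.frame` of covariates, row names = sample ids.
#' @export
simulate_metadata <- function(labels, effects, seed = 1L) {
  classes <- sort(unique(labels))
  with_seed(seed, {
    cols <- lapply(names(effects), function(v) {
      e <- effects[[v]]
      if (e$type == "continuous") {
        means <- rep_len(e$means, length(classes))
        rnorm(length(labels), mean = means[match(labels, classes)],
              sd = e$sd)
      } else if (e$type == "categorical") {
        probs <- e$probs
        if (!is.matrix(probs)) {
          probs <- matrix(probs, nrow = length(classes),
                          ncol = length(e$levels), byrow = TRUE)
        }
        if (any(abs(rowSums(probs) - 1) > 1e-9)) {
          stop_("level probabilities for '%s' must sum to 1", v)
        }
        idx <- vapply(labels, function(z) {
          sample.int(length(e$levels), 1,
                     prob = probs[match(z, classes), ])
        }, integer(1))
        factor(e$levels[idx], levels = e$levels)
      } else stop_("unknown effect type '%s'", e$type)
    })
    names(cols) <- names(effects)
    out <- as.data.frame(cols, check.names = FALSE)
    rownames(out) <- names(labels)
    out
  })
}

#' Preset: neonatal-style cohort
#'
#' Six mixture components emulating a very-preterm neonatal gut at about one
#' month of age: five classes each strongly dominated by a single driver
#' genus (Enterobacter-, Clostridium-, Escherichia-, Enterococcus- and
#' Staphylococcus-like, in cohort proportions 69:18:25:18:11) plus one
#' low-biomass class (18/159) whose library sizes fall below the
#' amplification threshold.
#'
#' @param n_samples cohort size (default 159).
#' @param seed integer seed.
#' @return A [cohort_config()].
#' @export
config_neonatal <- function(n_samples = 159, seed = 1L) {
  drivers <- c("Enterobacter", "Clostridium_ss1", "Escherichia",
               "Enterococcus", "Staphylococcus", "LowBiomassMarker")
  others <- sprintf("g%02d", seq_len(34))
  taxa <- c(drivers, others)
  cohort_config(
    n_samples = n_samples, n_taxa = length(taxa), K = 6,
    mixing_weights = c(69, 18, 25, 18, 11, 18) / 159,
    dirichlet_base = 0.08,
    driver_taxa = drivers,
    driver_boost = c(rep(400, 5), 1),
    depth_log_mean = c(rep(log(2e4), 5), log(60)),
    depth_log_sd = 0.5,
    failure_threshold = 1000,
    taxon_names = taxa,
    seed = seed)
}

#' Preset: childhood-style cohort
#'
#' Two moderately separated components emulating the early-childhood gut:
#' a majority Bacteroides-driven class and a minority Prevotella-driven
#' class (128:31) in which Bacteroides remains the second-ranked genus.
#'
#' @param n_samples cohort size (default 159).
#' @param seed integer seed.
#' @return A [cohort_config()].
#' @export
config_childhood <- function(n_samples = 159, seed = 1L) {
  drivers <- c("Bacteroides", "Prevotella")
  others <- c("Faecalibacterium", "Agathobacter", "Roseburia",
              "Ruminococcus", "Bifidobacterium", "Blautia",
              sprintf("g%02d", seq_len(24)))
  taxa <- c(drivers, others)
  base <- matrix(0.5, nrow = 2, ncol = length(taxa),
                 dimnames = NULL)
  base[2, 1] <- 4  # Bacteroides stays second-ranked in the Prevotella class
  cohort_config(
    n_samples = n_samples, n_taxa = length(taxa), K = 2,
    mixing_weights = c(128, 31) / 159,
    dirichlet_base = base,
    driver_taxa = drivers,
    driver_boost = c(30, 30),
    depth_log_mean = log(2e4),
    depth_log_sd = 0.4,
    failure_threshold = 0,
    taxon_names = taxa,
    seed = seed)
}
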