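# Seeded generators for trees, traits and morphometric tables. Every
# generator is a pure function of its arguments: a master seed plus a fixed
# per-generator offset selects an independent substream, so adding a new
# generator never perturbs the draws of the existing ones.

.SEED_OFFSETS <- c(tree = 101L, bm = 211L, binary = 307L, pgls = 401L,
                   morpho = 503L, disc = 601L)

.substream_seed <- function(seed, generator) {
  off <- .SEED_OFFSETS[[generator]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Synthetic study configuration
#'
#' Bundles the generative parameters for a full synthetic study emulating a
#' ~60-species comparative design: a pure-birth phylogeny, Brownian traits
#' with tunable phylogenetic signal, binary traits correlated with the EF
#' ratio, and replicate-level morphometric measurements whose eye and
#' funiculus areas scale isometrically with head size while the EF ratio
#' varies independently of size.
#'
#' @param seed master integer seed; recorded in every output.
#' @param n_species number of species (tips).
#' @param birth_rate pure-birth speciation rate (per unit time).
#' @param sigma2 Brownian rate of the continuous trait simulators.
#' @param lambda_true Pagel's lambda of simulated traits, in [0, 1].
#' @param beta_true regression coefficients (intercept, slope) for PGLS
#'   datasets.
#' @param binary_prevalence expected fraction of species scored 1.
#' @param isometry_slope log-log slope of area on head width in the
#'   morphometric generator (2 = isometry of an area on a length).
#' @param ef_log_sd standard deviation of the latent log EF allocation axis
#'   across species.
#' @param ef_lambda Pagel's lambda of the EF allocation axis (default 0:
#'   across real species the EF ratio shows essentially no phylogenetic
#'   signal, so the emulated trait is phylogeny-free by default).
#' @param n_replicates_per_species specimens measured per species.
#' @param measurement_cv multiplicative replicate measurement noise
#'   (coefficient of variation).
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, n_species = 62L, birth_rate = 1,
                             sigma2 = 1, lambda_true = 1,
                             beta_true = c(1, 0.5),
                             binary_prevalence = 0.4, isometry_slope = 2,
                             ef_log_sd = 0.4, ef_lambda = 0,
                             n_replicates_per_species = 5L,
                             measurement_cv = 0.05) {
  stopifnot(n_species >= 2, birth_rate > 0, sigma2 >= 0,
            lambda_true >= 0, lambda_true <= 1,
            ef_lambda >= 0, ef_lambda <= 1,
            binary_prevalence > 0, binary_prevalence < 1,
            ef_log_sd >= 0, n_replicates_per_species >= 1,
            measurement_cv >= 0)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 birth_rate = birth_rate, sigma2 = sigma2,
                 lambda_true = lambda_true, beta_true = beta_true,
                 binary_prevalence = binary_prevalence,
                 isometry_slope = isometry_slope, ef_log_sd = ef_log_sd,
                 ef_lambda = ef_lambda,
                 n_replicates_per_species =
                   as.integer(n_replicates_per_species),
                 measurement_cv = measurement_cv),
            class = "synthetic_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation: starting from two lineages at the root, waiting times
#' to the next speciation are exponential with rate `k * birth_rate` for `k`
#' extant lineages and the splitting lineage is chosen uniformly. After the
#' last split one further exponential waiting time is appended, so every tip
#' ends at the same depth (the tree is ultrametric). By default branch
#' lengths are rescaled to unit root-to-tip depth, which makes a Brownian
#' rate `sigma2` comparable across simulated trees.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed; the tree is a deterministic function of it.
#' @param rescale rescale total depth to 1 (default TRUE).
#' @return an ultrametric [ape::phylo] with tips `s01, s02, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed, rescale = TRUE) {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(.substream_seed(seed, "tree"))
  # node bookkeeping: parent id and the time each node's branch starts
  parent <- c(NA_integer_, 1L, 1L)
  start <- c(0, 0, 0)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * birth_rate)
    j <- active[sample.int(k, 1L)]
    id <- length(parent) + c(1L, 2L)
    parent <- c(parent, j, j)
    start <- c(start, t, t)
    active <- c(active[active != j], id)
  }
  t_end <- t + stats::rexp(1, rate = n_tips * birth_rate)

  n_nodes <- length(parent)
  is_tip <- !(seq_len(n_nodes) %in% parent)
  end <- rep(t_end, n_nodes)
  kids <- which(!is.na(parent))
  end[parent[kids]] <- start[kids]          # internal branch ends at its split

  # renumber to ape convention: tips 1..n, root n+1, internals follow
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)
  int_ids <- c(1L, setdiff(int_ids, 1L))    # root first
  newid <- integer(n_nodes)
  newid[tip_ids] <- seq_along(tip_ids)
  newid[int_ids] <- n_tips + seq_along(int_ids)
  edge <- cbind(newid[parent[kids]], newid[kids])
  lens <- end[kids] - start[kids]
  if (rescale) lens <- lens / t_end
  tree <- structure(list(edge = edge,
                         edge.length = lens,
                         tip.label = sprintf("s%02d", seq_len(n_tips)),
                         Nnode = length(int_ids)),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
}

#' Simulate a continuous trait under lambda-transformed Brownian motion
#'
#' Draws one trait vector from the multivariate normal with mean `root` and
#' covariance `sigma2 * V(lambda_true)`, where `V` is the tree's Brownian
#' covariance, via a Cholesky factor of the transformed covariance.
#'
#' @param tree an [ape::phylo] object.
#' @param sigma2 Brownian rate (>= 0; 0 gives a constant trait).
#' @param lambda_true Pagel's lambda of the generating process.
#' @param root root (ancestral) trait value.
#' @param seed integer seed.
#' @return named numeric vector in `tree$tip.label` order.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, lambda_true = 1, root = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  validate_phylogeny(tree)
  stopifnot(sigma2 >= 0)
  n <- length(tree$tip.label)
  x <- rep(root, n)
  names(x) <- tree$tip.label
  if (sigma2 > 0) {
    V <- lambda_transform(vcv_from_tree(tree), lambda_true)
    R <- .chol_factor(sigma2 * V)
    set.seed(.substream_seed(seed, "bm"))
    x <- x + drop(crossprod(R, stats::rnorm(n)))
    names(x) <- tree$tip.label
  }
  x
}

#' Simulate a binary trait with phylogenetic signal
#'
#' Latent-threshold model: a latent trait evolves under lambda-transformed
#' Brownian motion and species above the latent `(1 - prevalence)` quantile
#' are scored 1. Thresholding the latent trait (rather than iid Bernoulli
#' draws) preserves tunable phylogenetic signal in the binary column.
#'
#' @param tree an [ape::phylo] object.
#' @param prevalence target fraction of species scored 1, in [0, 1].
#' @param lambda_true lambda of the latent trait.
#' @param seed integer seed.
#' @return named 0/1 vector in tip order.
#' @export
simulate_binary_trait <- function(tree, prevalence = 0.4, lambda_true = 1,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(prevalence >= 0, prevalence <= 1)
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (prevalence <= 0) {
    return(stats::setNames(rep(0, n), tree$tip.label))
  }
  if (prevalence >= 1) {
    return(stats::setNames(rep(1, n), tree$tip.label))
  }
  latent <- simulate_bm_trait(tree, sigma2 = 1, lambda_true = lambda_true,
                              root = 0, seed = .substream_seed(seed, "binary"))
  thr <- stats::quantile(latent, 1 - prevalence, names = FALSE)
  stats::setNames(as.numeric(latent > thr), tree$tip.label)
}

#' Simulate a PGLS regression dataset
#'
#' Builds `X = [1, b]` with `b` a phylogenetically structured binary
#' predictor and `y = X beta_true + e`, where the errors are drawn from
#' `MVN(0, sigma2 * V(lambda_resid))`. Used as a recovery harness for
#' [pgls_fit()].
#'
#' @param tree an [ape::phylo] object.
#' @param beta_true length-2 coefficient vector (intercept, slope).
#' @param lambda_resid lambda of the residual covariance.
#' @param sigma2 residual Brownian rate.
#' @param binary_prevalence prevalence of the binary predictor.
#' @param seed integer seed.
#' @return list with `y` (named response) and `X` (design matrix with
#'   columns `intercept`, `predictor`).
#' @export
simulate_pgls_dataset <- function(tree, beta_true = c(1, 0.5),
                                  lambda_resid = 1, sigma2 = 1,
                                  binary_prevalence = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  validate_phylogeny(tree)
  stopifnot(length(beta_true) == 2L)
  s <- .substream_seed(seed, "pgls")
  b <- simulate_binary_trait(tree, prevalence = binary_prevalence,
                             lambda_true = 1, seed = s)
  e <- simulate_bm_trait(tree, sigma2 = sigma2, lambda_true = lambda_resid,
                         root = 0, seed = s + 1L)
  X <- cbind(intercept = 1, predictor = b)
  rownames(X) <- tree$tip.label
  y <- drop(X %*% beta_true) + e
  names(y) <- tree$tip.label
  list(y = y, X = X)
}

# shape constants for back-solving linear measurements from target areas;
# D. melanogaster-scale baselines (micrometres)
.MORPHO <- list(body0 = 2500, body_log_sd = 0.25, head_frac = 0.36,
                eye_area_coef = 0.74, fun_area_coef = 0.10,
                eye_aspect = 1.5,   # eye height = 1.5 * eye width
                fun_aspect = 2.5)   # funiculus length = 2.5 * width

#' Simulate a specimen-level morphometric table
#'
#' Generates per-replicate linear measurements whose derived traits have,
#' by construction, the structure the downstream analysis assumes:
#' log body length evolves by Brownian motion on the tree; head width is
#' proportional to body length; log eye and funiculus areas both scale with
#' `isometry_slope * log(head width)` (isometry), while a latent
#' "allocation axis" `z` (lambda-transformed Brownian with
#' `lambda = ef_lambda`, species-level SD `ef_log_sd`) shifts
#' log eye area by `+z/2` and log funiculus area by `-z/2`, so the EF ratio
#' (`exp(z)` times a constant) is independent of size by construction.
#' Linear measurements are recovered from the target areas through the exact
#' inverse of the surface-area formulas at fixed aspect ratios, then
#' perturbed per replicate by multiplicative lognormal noise with
#' coefficient of variation `measurement_cv`.
#'
#' @param config a [synthetic_config()].
#' @param tree an [ape::phylo] with `config$n_species` tips; defaults to a
#'   fresh pure-birth tree from the config seed.
#' @return data.frame in the specimen-table layout of
#'   [aggregate_species()], with one row per replicate.
#' @export
simulate_morphometric_table <- function(config, tree = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_species, config$birth_rate,
                          seed = config$seed)
  }
  validate_phylogeny(tree)
  m <- .MORPHO
  s <- .substream_seed(config$seed, "morpho")
  log_body <- simulate_bm_trait(tree, sigma2 = m$body_log_sd^2,
                                lambda_true = 1, root = log(m$body0),
                                seed = s)
  z <- if (config$ef_log_sd > 0) {
    simulate_bm_trait(tree, sigma2 = config$ef_log_sd^2,
                      lambda_true = config$ef_lambda, root = 0,
                      seed = s + 1L)
  } else stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label)

  body <- exp(log_body)
  head <- m$head_frac * body
  log_eye_area <- log(m$eye_area_coef) +
    config$isometry_slope * log(head) + z / 2
  log_fun_area <- log(m$fun_area_coef) +
    config$isometry_slope * log(head) - z / 2

  # invert the area formulas at fixed aspect ratios:
  # eye: height = a_e * width, r = w (1 + a_e/2) / 2, area = 2 pi r^2
  # funiculus: length = a_f * width, r = w (a_f + 1) / 4,
  #            area = 4 pi r^2 - pi (w/2)^2
  eye_w <- sqrt(exp(log_eye_area) / (2 * pi)) / ((1 + m$eye_aspect / 2) / 2)
  fun_geom <- 4 * pi * ((m$fun_aspect + 1) / 4)^2 - pi / 4
  fun_w <- sqrt(exp(log_fun_area) / fun_geom)

  nrep <- config$n_replicates_per_species
  cv <- config$measurement_cv
  set.seed(s + 2L)
  rows <- lapply(seq_along(tree$tip.label), function(i) {
    sp <- tree$tip.label[i]
    base <- c(body_length = body[[i]],
              head_width = head[[i]],
              eye_width = eye_w[[i]],
              eye_height = m$eye_aspect * eye_w[[i]],
              funiculus_length = m$fun_aspect * fun_w[[i]],
              funiculus_width = fun_w[[i]])
    noise <- matrix(exp(stats::rnorm(nrep * length(base), 0, cv)),
                    nrow = nrep)
    df <- as.data.frame(sweep(noise, 2, base, `*`))
    names(df) <- names(base)
    cbind(species = sp, replicate = sprintf("r%02d", seq_len(nrep)), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate imaginal-disc ratios paired with adult EF ratios
#'
#' Species fall into two groups (olfactory-biased and visually-biased disc
#' allocation) with group-specific mean disc ratios; the species-level log
#' disc ratio and log adult EF ratio are linked through a Gaussian copula so
#' that their population correlation equals `rho_adult` regardless of the
#' group separation. Each species contributes `n_replicates` disc
#' measurements sharing the species ratio (the antennal portion area varies
#' between mounts, the internal partition does not).
#'
#' @param n_species number of species, split evenly between the two groups.
#' @param group_means mean disc ratios of the two groups.
#' @param sd within-group SD of the species log disc ratio (0 puts every
#'   species exactly at its group mean).
#' @param rho_adult target Pearson correlation between log disc ratio and
#'   log adult EF ratio, in [-1, 1].
#' @param seed integer seed.
#' @param n_replicates disc mounts per species.
#' @param adult_ef optional named vector of adult EF ratios for the species
#'   to simulate discs for; when given, the disc ratios are generated
#'   conditionally on these values (correlation `rho_adult` on the log
#'   scale) instead of drawing fresh adult values, and groups become the
#'   median split of the disc ratios.
#' @return list with `discs` (data.frame `species`, `replicate`,
#'   `eye_portion_area`, `antennal_portion_area`, micrometres squared),
#'   `adult_ef` (named vector of adult EF ratios) and `group` (named 1/2).
#' @export
simulate_disc_data <- function(n_species = 12L, group_means = c(1.5, 2.5),
                               sd = 0.1, rho_adult = 0.8, seed,
                               n_replicates = 3L, adult_ef = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(group_means) == 2L, all(group_means > 0),
            abs(rho_adult) <= 1, sd >= 0)
  set.seed(.substream_seed(seed, "disc"))
  # population SD of log disc ratio: equal-weight two-point mixture of the
  # group means plus the within-group spread
  between_sd <- abs(diff(log(group_means))) / 2
  s_disc <- sqrt(between_sd^2 + sd^2)
  ef_sd <- 0.3
  if (is.null(adult_ef)) {
    stopifnot(n_species >= 2L)
    sp <- sprintf("s%02d", seq_len(n_species))
    grp <- rep(1:2, length.out = n_species)
    mu_g <- log(group_means)[grp]
    u <- stats::rnorm(n_species)
    log_disc <- mu_g + sd * u
    v <- stats::rnorm(n_species)
    log_ef <- log(5) +
      rho_adult * (ef_sd / s_disc) * (log_disc - mean(mu_g)) +
      ef_sd * sqrt(1 - rho_adult^2) * v
    adult_ef <- stats::setNames(exp(log_ef), sp)
  } else {
    stopifnot(!is.null(names(adult_ef)), all(adult_ef > 0),
              length(adult_ef) >= 2L)
    n_species <- length(adult_ef)
    sp <- names(adult_ef)
    z_ef <- (log(adult_ef) - mean(log(adult_ef))) /
      max(stats::sd(log(adult_ef)), .Machine$double.eps)
    log_disc <- mean(log(group_means)) +
      s_disc * (rho_adult * z_ef +
                  sqrt(1 - rho_adult^2) * stats::rnorm(n_species))
    grp <- as.integer(log_disc > stats::median(log_disc)) + 1L
  }

  ant_base <- 15000   # antennal disc portion area, square micrometres
  rows <- lapply(seq_len(n_species), function(i) {
    ant <- ant_base * exp(stats::rnorm(n_replicates, 0, 0.1))
    data.frame(species = sp[i],
               replicate = sprintf("r%02d", seq_len(n_replicates)),
               eye_portion_area = exp(log_disc[i]) * ant,
               antennal_portion_area = ant)
  })
  discs <- do.call(rbind, rows)
  rownames(discs) <- NULL
  list(discs = discs, adult_ef = adult_ef,
       group = stats::setNames(grp, sp))
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates the tree, specimen table, per-species binary trait table and
#' disc data for one synthetic study and writes them as plain-text files:
#' `tree.nwk`, `specimens.csv`, `traits.csv`, `discs.csv` and `config.json`
#' (the configuration echoed back). The binary columns are latent-threshold
#' traits whose latent axis mixes the EF allocation axis with independent
#' noise, so they correlate with the EF ratio as wing pigmentation and
#' light-dependent courtship do with relative eye size.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = config$seed)
  specimens <- simulate_morphometric_table(config, tree)

  # binary traits loaded on the EF allocation axis plus independent noise
  s <- .substream_seed(config$seed, "morpho")
  z <- simulate_bm_trait(tree, sigma2 = config$ef_log_sd^2,
                         lambda_true = config$ef_lambda, root = 0,
                         seed = s + 1L)
  set.seed(.substream_seed(config$seed, "binary") + 7L)
  mk_bin <- function(weight) {
    latent <- weight * scale(z)[, 1] +
      sqrt(1 - weight^2) * stats::rnorm(length(z))
    thr <- stats::quantile(latent, 1 - config$binary_prevalence,
                           names = FALSE)
    as.numeric(latent > thr)
  }
  binaries <- data.frame(species = tree$tip.label,
                         wing_pigmentation_female = mk_bin(0.7),
                         wing_pigmentation_male = mk_bin(0.7),
                         light_courtship = mk_bin(0.8))

  # disc data for a stratified subset spanning the EF range, conditioned on
  # each species' true adult EF ratio (exp(z) up to a shape constant)
  adult_ef <- .MORPHO$eye_area_coef / .MORPHO$fun_area_coef * exp(z)
  n_disc <- min(12L, config$n_species)
  sel <- unique(round(seq(1, config$n_species, length.out = n_disc)))
  sel_sp <- names(sort(adult_ef))[sel]
  disc <- simulate_disc_data(seed = config$seed,
                             adult_ef = adult_ef[sel_sp])

  paths <- list(tree = file.path(dir, "tree.nwk"),
                specimens = file.path(dir, "specimens.csv"),
                traits = file.path(dir, "traits.csv"),
                discs = file.path(dir, "discs.csv"),
                config = file.path(dir, "config.json"))
  write_newick(tree, paths$tree)
  utils::write.csv(specimens, paths$specimens, row.names = FALSE)
  utils::write.csv(binaries, paths$traits, row.names = FALSE)
  utils::write.csv(disc$discs, paths$discs, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(tree = tree, specimens = specimens, binaries = binaries,
                 disc = disc, config = config, paths = paths))
}
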