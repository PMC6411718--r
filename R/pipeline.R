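#' Configuration for a full comparative analysis
#'
#' Collects input paths, column choices and statistical settings for
#' [run_full_analysis()]. Every convention flag and the seed are echoed into
#' the report's provenance block so a report is regenerable from its config
#' alone.
#'
#' @param tree path to a Newick tree with branch lengths.
#' @param specimens path to the specimen measurement CSV (columns `species`,
#'   `replicate`, `body_length`, `head_width`, `eye_width`, `eye_height`,
#'   `funiculus_length`, `funiculus_width`).
#' @param traits optional path to a per-species binary trait CSV (columns
#'   `species`, `wing_pigmentation_female`, `wing_pigmentation_male`,
#'   `light_courtship`).
#' @param counts optional sensillum count CSV (columns `species`,
#'   `replicate`, `side`, `trichoid`, `basiconic`, `coeloconic`).
#' @param discs optional disc CSV (columns `species`, `replicate`,
#'   `eye_portion_area`, `antennal_portion_area`) paired with adult EF
#'   ratios from the specimen table.
#' @param trait_column species-level trait analysed for phylogenetic signal.
#' @param n_perm permutations for the Blomberg K test.
#' @param seed integer seed for the permutation stream.
#' @param pgls_mode `"ml_lambda"` or `"brownian"`.
#' @param eye_convention,funiculus_surface geometry conventions, passed to
#'   [aggregate_species()].
#' @param out_dir optional output directory for written reports.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(tree, specimens, traits = NULL, counts = NULL,
                            discs = NULL, trait_column = "ef_ratio",
                            n_perm = 999L, seed = 42L,
                            pgls_mode = c("ml_lambda", "brownian"),
                            eye_convention = "width-halfheight",
                            funiculus_surface = "full",
                            out_dir = NULL) {
  pgls_mode <- match.arg(pgls_mode)
  for (p in c(tree, specimens, traits, counts, discs)) {
    if (!file.exists(p)) stop("input file does not exist: ", p,
                              call. = FALSE)
  }
  structure(list(tree = tree, specimens = specimens, traits = traits,
                 counts = counts, discs = discs,
                 trait_column = trait_column, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), pgls_mode = pgls_mode,
                 eye_convention = eye_convention,
                 funiculus_surface = funiculus_surface, out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full comparative analysis
#'
#' Orchestrates the pipeline end to end: aggregate specimen measurements to
#' a species trait table, compute the EF ratio, align traits to the tree
#' (pruning explicitly), estimate Pagel's lambda by ML, compute Blomberg's K
#' with its permutation test, run a PGLS of the focal trait on each binary
#' trait, correlate disc ratios with adult EF ratios when disc data are
#' given, and run the isometry checks (allometry of eye/funiculus area on
#' head width, and a multiple regression of the EF ratio on the size
#' measurements). Every number in the returned bundle is a deterministic
#' function of the inputs and the config.
#'
#' @param config an [analysis_config()].
#' @return a list of class `"report_bundle"`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  tree <- stage("read_tree", read_newick(config$tree))
  specimens <- stage("read_specimens",
                     utils::read.csv(config$specimens,
                                     stringsAsFactors = FALSE))
  counts <- if (!is.null(config$counts)) {
    stage("read_counts", utils::read.csv(config$counts,
                                         stringsAsFactors = FALSE))
  }
  binaries <- if (!is.null(config$traits)) {
    stage("read_traits", utils::read.csv(config$traits,
                                         stringsAsFactors = FALSE))
  }

  traits <- stage("aggregate_species",
                  aggregate_species(specimens, counts = counts,
                                    binaries = binaries,
                                    eye_convention = config$eye_convention,
                                    funiculus_surface =
                                      config$funiculus_surface))

  x_all <- stats::setNames(traits[[config$trait_column]], traits$species_id)
  al <- stage("align_traits_to_tree",
              align_traits_to_tree(x_all, tree, quiet = TRUE))
  x <- al$x
  ptree <- al$tree

  lam <- stage("fit_lambda_ml", fit_lambda_ml(x, ptree))
  kk <- stage("k_permutation_test",
              k_permutation_test(x, ptree, n_perm = config$n_perm,
                                 seed = config$seed))

  pgls <- list()
  if (!is.null(binaries)) {
    for (bt in intersect(c("wing_pigmentation_female",
                           "wing_pigmentation_male", "light_courtship"),
                         names(binaries))) {
      b <- stats::setNames(traits[[bt]], traits$species_id)
      ok <- names(b)[!is.na(b)]
      ok <- intersect(ok, ptree$tip.label)
      if (length(ok) < 4L) next
      sub <- align_traits_to_tree(x[ok], ptree, quiet = TRUE)
      X <- cbind(intercept = 1, predictor = b[sub$tree$tip.label])
      colnames(X) <- c("intercept", bt)
      rownames(X) <- sub$tree$tip.label
      pgls[[bt]] <- stage(paste0("pgls_", bt),
                          pgls_fit(sub$x, X, sub$tree,
                                   mode = config$pgls_mode))
    }
    if (length(pgls) > 1L) {
      raw_p <- vapply(pgls, function(f) unname(f$p_values[2L]), numeric(1))
      holm <- stats::p.adjust(raw_p, method = "holm")
      for (i in seq_along(pgls)) pgls[[i]]$p_holm <- unname(holm[i])
    }
  }

  disc_cor <- NULL
  if (!is.null(config$discs)) {
    discs <- stage("read_discs", utils::read.csv(config$discs,
                                                 stringsAsFactors = FALSE))
    dr <- tapply(disc_ratio(discs$eye_portion_area,
                            discs$antennal_portion_area),
                 discs$species, mean)
    shared <- intersect(names(dr), traits$species_id)
    if (length(shared) >= 3L) {
      ef <- stats::setNames(traits$ef_ratio, traits$species_id)[shared]
      disc_cor <- stage("trait_correlation",
                        c(trait_correlation(log(dr[shared]), log(ef)),
                          list(n_species = length(shared))))
    }
  }

  sp <- traits[match(ptree$tip.label, traits$species_id), ]
  # head width per species comes from the specimen means
  head_w <- tapply(specimens$head_width, specimens$species, mean)
  head_w <- head_w[ptree$tip.label]
  allom <- list(
    eye_area_vs_head = stage("allometry_eye",
      allometry_fit(head_w, sp$eye_area, expected_slope = 2)),
    funiculus_area_vs_head = stage("allometry_funiculus",
      allometry_fit(head_w, sp$funiculus_area, expected_slope = 2)),
    ef_vs_body = stage("allometry_ef",
      allometry_fit(tapply(specimens$body_length, specimens$species,
                           mean)[ptree$tip.label],
                    sp$ef_ratio, expected_slope = 0)))

  body_l <- tapply(specimens$body_length, specimens$species,
                   mean)[ptree$tip.label]
  mr <- stage("multiple_regression",
              multiple_regression(log(sp$ef_ratio),
                                  cbind(intercept = 1,
                                        log_body = log(body_l),
                                        log_head = log(head_w))))

  structure(list(trait_table = traits,
                 lambda = lam,
                 k = kk,
                 pgls = pgls,
                 disc_correlation = disc_cor,
                 allometry = allom,
                 size_regression = mr,
                 dropped_from_tree = al$dropped_from_tree,
                 dropped_from_data = al$dropped_from_data,
                 provenance = list(config = unclass(config),
                                   n_species_analysed =
                                     length(ptree$tip.label),
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "phylosense")))),
            class = "report_bundle")
}

.sig6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

.bundle_as_list <- function(bundle) {
  num <- function(v) lapply(as.list(v), .sig6)
  lam <- bundle$lambda
  kk <- bundle$k
  out <- list(
    n_species = bundle$provenance$n_species_analysed,
    lambda = list(lambda = .sig6(lam$lambda), sigma2 = .sig6(lam$sigma2),
                  loglik = .sig6(lam$loglik),
                  p_vs_zero = .sig6(lam$p_vs_zero),
                  p_vs_one = .sig6(lam$p_vs_one)),
    k = list(k = .sig6(kk$k), p_perm = .sig6(kk$p_perm),
             n_perm = kk$n_perm, seed = kk$seed),
    pgls = lapply(bundle$pgls, function(f) {
      r <- list(coefficients = num(f$coefficients),
                standard_errors = num(f$standard_errors),
                t_values = num(f$t_values),
                p_values = num(f$p_values),
                lambda_used = .sig6(f$lambda_used),
                sigma2 = .sig6(f$sigma2), df = f$df,
                mode = f$correlation_mode)
      if (!is.null(f$p_holm)) r$p_holm <- .sig6(f$p_holm)
      r
    }),
    allometry = lapply(bundle$allometry, function(a)
      list(slope = .sig6(a$slope), slope_ci = lapply(
             as.list(a$slope_ci), .sig6),
           expected_slope = a$expected_slope,
           p_isometry = .sig6(a$p_isometry), n = a$n)),
    size_regression = list(
      coefficients = num(bundle$size_regression$coefficients),
      p_values = num(bundle$size_regression$p_values),
      df = bundle$size_regression$df),
    dropped_from_tree = as.list(bundle$dropped_from_tree),
    dropped_from_data = as.list(bundle$dropped_from_data),
    provenance = bundle$provenance)
  if (!is.null(bundle$disc_correlation)) {
    dc <- bundle$disc_correlation
    out$disc_correlation <- list(r = .sig6(dc$r), p = .sig6(dc$p),
                                 df = dc$df, n_species = dc$n_species)
  }
  out
}

#' Write an analysis report
#'
#' Serializes a [run_full_analysis()] bundle to JSON (stable key order,
#' floats at 6 significant digits) or to a markdown summary mirroring the
#' JSON content. Writing the same bundle twice produces byte-identical
#' files; optional sections absent from the analysis are omitted rather
#' than null-filled.
#'
#' @param bundle a `report_bundle`.
#' @param format `"json"` or `"markdown"`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_report <- function(bundle, format = c("json", "markdown"), file) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "report_bundle"))
  lst <- .bundle_as_list(bundle)
  if (format == "json") {
    jsonlite::write_json(lst, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    ln <- c("# Comparative sensory-investment analysis", "",
            sprintf("Species analysed: %d", lst$n_species), "",
            "## Phylogenetic signal of the focal trait", "",
            sprintf("- Pagel's lambda (ML): %.6g (p vs 0 = %.4g, p vs 1 = %.4g)",
                    lst$lambda$lambda, lst$lambda$p_vs_zero,
                    lst$lambda$p_vs_one),
            sprintf("- Blomberg's K: %.4f (permutation p = %.4g, %d permutations, seed %d)",
                    lst$k$k, lst$k$p_perm, lst$k$n_perm, lst$k$seed), "")
    if (length(lst$pgls) > 0L) {
      ln <- c(ln, "## PGLS of the focal trait on binary traits", "")
      for (nm in names(lst$pgls)) {
        f <- lst$pgls[[nm]]
        ln <- c(ln, sprintf(
          "- %s: slope = %.4g (SE %.4g), p = %.4g%s [lambda = %.4g, %s]",
          nm, f$coefficients[[2]], f$standard_errors[[2]],
          f$p_values[[2]],
          if (!is.null(f$p_holm)) sprintf(", Holm p = %.4g", f$p_holm)
          else "",
          f$lambda_used, f$mode))
      }
      ln <- c(ln, "")
    }
    if (!is.null(lst$disc_correlation)) {
      ln <- c(ln, "## Disc ratio vs adult EF ratio", "",
              sprintf("- Pearson r (log scale) = %.4f, p = %.4g (n = %d species)",
                      lst$disc_correlation$r, lst$disc_correlation$p,
                      lst$disc_correlation$n_species), "")
    }
    ln <- c(ln, "## Size scaling", "")
    for (nm in names(lst$allometry)) {
      a <- lst$allometry[[nm]]
      ln <- c(ln, sprintf(
        "- %s: slope = %.4f (CI %.4f..%.4f), expected %g, isometry p = %.4g",
        nm, a$slope, a$slope_ci[[1]], a$slope_ci[[2]], a$expected_slope,
        a$p_isometry))
    }
    ln <- c(ln, "", sprintf("Seed: %d; PGLS mode: %s; eye convention: %s",
                            lst$provenance$config$seed,
                            lst$provenance$config$pgls_mode,
                            lst$provenance$config$eye_convention))
    writeLines(ln, file)
  }
  invisible(file)
}

#' Write the species trait table as CSV
#'
#' Deterministic column order, 6 significant digits on the derived traits.
#'
#' @param traits output of [aggregate_species()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_trait_table <- function(traits, file) {
  cols <- c("species_id", "eye_area", "funiculus_area", "ef_ratio",
            "ommatidia", "trichoid_total", "sensilla_density",
            "wing_pigmentation_female", "wing_pigmentation_male",
            "light_courtship", "n_replicates")
  out <- traits[cols]
  for (cc in cols) {
    if (is.numeric(out[[cc]])) out[[cc]] <- signif(out[[cc]], 6)
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
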