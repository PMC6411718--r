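#' Aggregate specimen-level measurements into a species trait table
#'
#' Raw linear measurements are averaged across replicates within each species
#' (3-8 female specimens per species is typical) and the derived traits -
#' surface areas, the EF ratio and sensillum density - are then computed from
#' those mean measurements, not averaged over per-replicate derivations. This
#' keeps the derived traits order-invariant in the replicates and matches the
#' convention of averaging the raw widths and heights first.
#'
#' @param specimens data.frame with columns `species`, `replicate`,
#'   `body_length`, `head_width`, `eye_width`, `eye_height`,
#'   `funiculus_length`, `funiculus_width` (micrometres, all > 0).
#' @param counts optional data.frame with columns `species`, `replicate`,
#'   `side` (`"anterior"`, `"posterior"` or `"whole"`), `trichoid`,
#'   `basiconic`, `coeloconic` (non-negative integer counts).
#' @param ommatidia optional data.frame with columns `species`, `replicate`,
#'   `ommatidia`.
#' @param binaries optional per-species data.frame with columns `species`,
#'   `wing_pigmentation_female`, `wing_pigmentation_male`, `light_courtship`
#'   (0/1; pigmentation present = 1, light-dependent or light-enhanced
#'   courtship = 1).
#' @param eye_convention,funiculus_surface conventions passed to
#'   [eye_surface_area()] and [funiculus_surface_area()].
#' @return data.frame with one row per species and columns `species_id`,
#'   `eye_area`, `funiculus_area`, `ef_ratio`, `ommatidia`, `trichoid_total`,
#'   `sensilla_density`, `wing_pigmentation_female`, `wing_pigmentation_male`,
#'   `light_courtship`, `n_replicates`.
#' @export
aggregate_species <- function(specimens, counts = NULL, ommatidia = NULL,
                              binaries = NULL,
                              eye_convention = "width-halfheight",
                              funiculus_surface = "full") {
  meas_cols <- c("body_length", "head_width", "eye_width", "eye_height",
                 "funiculus_length", "funiculus_width")
  need <- c("species", "replicate", meas_cols)
  if (!all(need %in% names(specimens))) {
    stop("specimen table is missing columns: ",
         paste(setdiff(need, names(specimens)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(specimens) == 0L) stop("empty specimen table", call. = FALSE)
  for (cc in meas_cols) .check_positive_named(specimens[[cc]], cc)
  dup <- duplicated(specimens[c("species", "replicate")])
  if (any(dup)) {
    stop("replicate ids are not unique within species: rows ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }

  sp <- sort(unique(specimens$species))
  means <- do.call(rbind, lapply(sp, function(s) {
    g <- specimens[specimens$species == s, , drop = FALSE]
    data.frame(species_id = s,
               as.list(colMeans(g[meas_cols])),
               n_replicates = nrow(g))
  }))

  eye_area <- eye_surface_area(means$eye_width, means$eye_height,
                               convention = eye_convention)
  fun_area <- funiculus_surface_area(means$funiculus_length,
                                     means$funiculus_width,
                                     surface = funiculus_surface)

  out <- data.frame(species_id = means$species_id,
                    eye_area = eye_area,
                    funiculus_area = fun_area,
                    ef_ratio = ef_ratio(eye_area, fun_area),
                    ommatidia = NA_real_,
                    trichoid_total = NA_real_,
                    sensilla_density = NA_real_,
                    wing_pigmentation_female = NA_real_,
                    wing_pigmentation_male = NA_real_,
                    light_courtship = NA_real_,
                    n_replicates = means$n_replicates)

  if (!is.null(counts)) {
    if (!all(c("species", "side", "trichoid", "basiconic", "coeloconic")
             %in% names(counts))) {
      stop("sensillum count table is missing required columns", call. = FALSE)
    }
    bad <- !counts$side %in% c("anterior", "posterior", "whole")
    if (any(bad)) {
      stop("unknown sensillum 'side' values: ",
           paste(unique(counts$side[bad]), collapse = ", "), call. = FALSE)
    }
    cts <- counts[c("trichoid", "basiconic", "coeloconic")]
    if (any(cts < 0) || any(cts != floor(cts))) {
      stop("sensillum counts must be non-negative integers", call. = FALSE)
    }
    for (i in seq_along(out$species_id)) {
      s <- out$species_id[i]
      g <- counts[counts$species == s, , drop = FALSE]
      if (nrow(g) == 0L) next
      # replicate-level whole-antenna trichoid total: the 'whole' row when
      # present, otherwise anterior + posterior summed within the replicate
      tri <- vapply(split(g, g$replicate), function(r) {
        if (any(r$side == "whole")) sum(r$trichoid[r$side == "whole"])
        else sum(r$trichoid)
      }, numeric(1))
      out$trichoid_total[i] <- mean(tri)
      ant <- g[g$side == "anterior", , drop = FALSE]
      if (nrow(ant) > 0L) {
        n_ant <- mean(ant$trichoid + ant$basiconic + ant$coeloconic)
        out$sensilla_density[i] <- sensilla_density(n_ant,
                                                    out$funiculus_area[i])
      }
    }
  }

  if (!is.null(ommatidia)) {
    for (i in seq_along(out$species_id)) {
      g <- ommatidia[ommatidia$species == out$species_id[i], , drop = FALSE]
      if (nrow(g) > 0L) out$ommatidia[i] <- mean(g$ommatidia)
    }
  }

  if (!is.null(binaries)) {
    bc <- c("wing_pigmentation_female", "wing_pigmentation_male",
            "light_courtship")
    idx <- match(out$species_id, binaries$species)
    for (cc in intersect(bc, names(binaries))) {
      out[[cc]] <- binaries[[cc]][idx]
    }
  }

  rownames(out) <- NULL
  out
}

.check_positive_named <- function(v, nm) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("invalid measurement: column '", nm,
         "' contains non-positive or non-finite values", call. = FALSE)
  }
}
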