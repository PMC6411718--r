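#' Eye surface area from frontal-view width and height
#'
#' Models the compound eye as a half ellipsoid and approximates its surface
#' with the half-sphere formula `2 * pi * r^2`. The default radius convention
#' combines the eye width with half the eye height,
#' `r = (eye_width + eye_height / 2) / 2`; because the wording of that rule is
#' ambiguous in the field, the alternative reading that halves both axes,
#' `r = (eye_width / 2 + eye_height / 2) / 2`, is available via `convention`.
#'
#' @param eye_width eye width in micrometres (> 0); vectorised.
#' @param eye_height eye height in micrometres (> 0); vectorised.
#' @param convention radius rule: `"width-halfheight"` (default) or
#'   `"halfwidth-halfheight"`.
#' @return eye surface area in square micrometres.
#' @examples
#' eye_surface_area(2, 4)   # r = 2, area = 8 * pi
#' eye_surface_area(400, 600)
#' @export
eye_surface_area <- function(eye_width, eye_height,
                             convention = c("width-halfheight",
                                            "halfwidth-halfheight")) {
  convention <- match.arg(convention)
  .check_positive(eye_width = eye_width, eye_height = eye_height)
  r <- switch(convention,
    "width-halfheight"     = (eye_width + eye_height / 2) / 2,
    "halfwidth-halfheight" = (eye_width / 2 + eye_height / 2) / 2
  )
  2 * pi * r^2
}

#' Funiculus surface area from length and width
#'
#' Models the funiculus (third antennal segment, the main olfactory surface)
#' as a complete ovoid: sphere surface `4 * pi * r^2` with
#' `r = (length / 2 + width / 2) / 2`, minus the circular base area
#' `pi * (width / 2)^2` where the funiculus attaches to the pedicel. The
#' half-ellipsoid alternative (`2 * pi * r^2` minus the base) is available
#' via `surface`.
#'
#' @param funiculus_length funiculus length in micrometres (> 0); vectorised.
#' @param funiculus_width funiculus width in micrometres (> 0); vectorised.
#' @param surface `"full"` ovoid (default) or `"half"`.
#' @return funiculus surface area in square micrometres.
#' @examples
#' funiculus_surface_area(2, 2)   # 4*pi - pi = 3*pi
#' funiculus_surface_area(250, 100)
#' @export
funiculus_surface_area <- function(funiculus_length, funiculus_width,
                                   surface = c("full", "half")) {
  surface <- match.arg(surface)
  .check_positive(funiculus_length = funiculus_length,
                  funiculus_width = funiculus_width)
  r <- (funiculus_length / 2 + funiculus_width / 2) / 2
  sphere <- if (surface == "full") 4 * pi * r^2 else 2 * pi * r^2
  area <- sphere - pi * (funiculus_width / 2)^2
  if (any(area <= 0)) {
    stop("funiculus geometry error: non-positive surface area (width ",
         "much larger than length); offending rows: ",
         paste(which(area <= 0), collapse = ", "), call. = FALSE)
  }
  area
}

#' Eye-to-funiculus ratio
#'
#' The study's central sensory-allocation trait: eye surface area divided by
#' funiculus surface area. Dimensionless and invariant under a common
#' rescaling of both areas.
#'
#' @param eye_area eye surface area, square micrometres (> 0).
#' @param funiculus_area funiculus surface area, square micrometres (> 0).
#' @return the EF ratio (dimensionless).
#' @export
ef_ratio <- function(eye_area, funiculus_area) {
  .check_positive(eye_area = eye_area, funiculus_area = funiculus_area)
  eye_area / funiculus_area
}

#' Sensillum density on the anterior funiculus surface
#'
#' Density is the sensillum count divided by half the funiculus surface area
#' (one anterior or posterior face exposes half the ovoid).
#'
#' @param sensilla_number non-negative sensillum count.
#' @param funiculus_surface funiculus surface area, square micrometres (> 0).
#' @return sensilla per square micrometre.
#' @examples
#' sensilla_density(100, 200)  # 1.0
#' @export
sensilla_density <- function(sensilla_number, funiculus_surface) {
  if (any(sensilla_number < 0)) {
    stop("invalid measurement: sensilla_number must be non-negative",
         call. = FALSE)
  }
  .check_positive(funiculus_surface = funiculus_surface)
  sensilla_number / (0.5 * funiculus_surface)
}

#' Eye-antennal imaginal disc ratio
#'
#' Ratio of the eye portion area to the antennal portion area of the larval
#' eye-antennal imaginal disc, the developmental precursor of both adult
#' structures.
#'
#' @param eye_portion_area area of the eye portion, square micrometres (> 0).
#' @param antennal_portion_area area of the antennal portion (> 0).
#' @return dimensionless disc ratio.
#' @export
disc_ratio <- function(eye_portion_area, antennal_portion_area) {
  .check_positive(eye_portion_area = eye_portion_area,
                  antennal_portion_area = antennal_portion_area)
  eye_portion_area / antennal_portion_area
}

#' Neuropil volume ratios
#'
#' Ratios of optic lobe (OL), antennal lobe (AL) and central brain volumes
#' that index relative visual and olfactory investment in the brain. The
#' central brain volume excludes the AL, so the three ratios satisfy
#' `ol_al == ol_central / al_central` exactly.
#'
#' @param optic_lobe OL volume, cubic micrometres (> 0).
#' @param antennal_lobe AL volume, cubic micrometres (> 0).
#' @param central_brain central-brain volume excluding the AL (> 0).
#' @return a list with components `ol_al`, `ol_central`, `al_central`.
#' @export
volume_ratios <- function(optic_lobe, antennal_lobe, central_brain) {
  .check_positive(optic_lobe = optic_lobe, antennal_lobe = antennal_lobe,
                  central_brain = central_brain)
  list(ol_al      = optic_lobe / antennal_lobe,
       ol_central = optic_lobe / central_brain,
       al_central = antennal_lobe / central_brain)
}

#' Two-choice attraction index
#'
#' Symmetric preference index `(n_test - n_control) / (n_test + n_control)`
#' for a two-trap assay, bounded in [-1, 1]; 0 means no preference, 1 means
#' every captured fly chose the test trap.
#'
#' @param n_test flies captured in the test trap (>= 0).
#' @param n_control flies captured in the control trap (>= 0).
#' @return attraction index in [-1, 1].
#' @export
attraction_index <- function(n_test, n_control) {
  if (any(n_test < 0) || any(n_control < 0)) {
    stop("invalid measurement: counts must be non-negative", call. = FALSE)
  }
  total <- n_test + n_control
  if (any(total == 0)) {
    stop("undefined attraction index: no flies captured in either trap",
         call. = FALSE)
  }
  (n_test - n_control) / total
}

# shared positivity check; names its offending argument
.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("invalid measurement: '", nm, "' must be finite and strictly ",
           "positive", call. = FALSE)
    }
  }
  invisible(TRUE)
}
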