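#' Default sex-specific body-segment parameter table
#'
#' Returns the segment parameter table for the modeled upper body of a seated
#' subject: trunk (hip joint to shoulder line, the full trunk length), head and
#' neck, and both upper arms and forearms. Mass fractions are the Plagenhoef
#' (1983) water-immersion statistics; the proximal CoM coefficient `k` places
#' each segment's center of mass at fraction `k` of the segment length measured
#' from the proximal joint (forearm/upper arm/trunk: 43/43.6/63 % for males,
#' 43.4/45.8/56.9 % for females).
#'
#' Hands are not part of the default set: the 25-keypoint layout carries no
#' keypoint distal to the wrist, so a hand segment cannot be defined by a joint
#' pair. Lower limbs are excluded because the seated analysis is referenced to
#' the hip joint.
#'
#' @param sex `"male"` or `"female"`.
#' @param table optional replacement parameter table in the same format as
#'   `segment_parameter_table()` (columns `name, side, proximal_idx, distal_idx,
#'   mass_fraction_male, mass_fraction_female, k_male, k_female`).
#' @return A data frame with columns `name`, `side`, `proximal_idx`,
#'   `distal_idx` (0-based keypoint indices), `mass_fraction`, `k`.
#' @export
#' @examples
#' default_segment_table("male")
default_segment_table <- function(sex = c("male", "female"), table = NULL) {
  sex <- match.arg(sex)
  tab <- if (is.null(table)) segment_parameter_table() else table
  suffix <- if (sex == "male") "male" else "female"
  out <- data.frame(
    name = tab$name,
    side = tab$side,
    proximal_idx = as.integer(tab$proximal_idx),
    distal_idx = as.integer(tab$distal_idx),
    mass_fraction = tab[[paste0("mass_fraction_", suffix)]],
    k = tab[[paste0("k_", suffix)]],
    stringsAsFactors = FALSE
  )
  validate_segment_table(out)
  out
}

#' Read the shipped segment parameter file
#'
#' @return Data frame with one row per segment and sex-specific columns.
#' @export
segment_parameter_table <- function() {
  path <- system.file("extdata", "segment_parameters.csv", package = "hypocom")
  if (path == "") stop("segment parameter file not found; is the package installed?")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

validate_segment_table <- function(tab) {
  stopifnot(
    all(tab$k >= 0 & tab$k <= 1),
    all(tab$mass_fraction > 0 & tab$mass_fraction < 1),
    all(tab$proximal_idx != tab$distal_idx),
    all(tab$proximal_idx %in% 0:24), all(tab$distal_idx %in% 0:24)
  )
  s <- sum(tab$mass_fraction)
  if (s <= 0 || s > 1) stop("segment mass fractions must sum to a value in (0, 1]")
  invisible(tab)
}

#' Construct a body model
#'
#' Bundles a subject's total mass with a segment parameter table (and optional
#' per-segment volumes, dm^3) into the model consumed by [body_com()].
#'
#' @param sex `"male"` or `"female"`.
#' @param total_mass total body mass, kg.
#' @param segments segment table as returned by [default_segment_table()].
#' @param segment_volumes optional named numeric vector of per-segment volumes
#'   (dm^3), names matching `segments$name`.
#' @return An object of class `body_model`.
#' @export
body_model <- function(sex = c("male", "female"), total_mass,
                       segments = default_segment_table(sex),
                       segment_volumes = NULL) {
  sex <- match.arg(sex)
  if (!is.numeric(total_mass) || length(total_mass) != 1L || !is.finite(total_mass) ||
      total_mass <= 0) {
    stop("total_mass must be a single positive number (kg)")
  }
  validate_segment_table(segments)
  if (!is.null(segment_volumes)) {
    if (is.null(names(segment_volumes)) ||
        !all(names(segment_volumes) %in% segments$name)) {
      stop("segment_volumes must be named after segments in the table")
    }
  }
  structure(
    list(sex = sex, total_mass = total_mass, segments = segments,
         segment_volumes = segment_volumes),
    class = "body_model"
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat("Body model (", x$sex, "), total mass ", format(x$total_mass), " kg, ",
      nrow(x$segments), " segments covering ",
      format(100 * sum(x$segments$mass_fraction)), "% of body mass\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Segment center of mass
#'
#' CoM of a body segment whose mass center sits at fraction `k` of the segment
#' length measured from the proximal joint: `p_prox + k * (p_dist - p_prox)`.
#'
#' @param p_prox,p_dist 3D joint coordinates (cm), length-3 numeric.
#' @param k proximal CoM coefficient in `[0, 1]`.
#' @return Length-3 numeric, the segment CoM (cm).
#' @export
#' @examples
#' segment_com(c(0, 0, 0), c(10, 0, 0), 0.43)  # 4.3 cm from the proximal end
segment_com <- function(p_prox, p_dist, k) {
  if (!is_finite_point(p_prox) || !is_finite_point(p_dist)) {
    stop("segment endpoints must be finite length-3 numeric vectors")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0 || k > 1) {
    stop("k must be a single number in [0, 1]")
  }
  p_prox + k * (p_dist - p_prox)
}
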