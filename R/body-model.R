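# Subject description and planar link-segment inertial model.
#
# Segment lengths are derived from stature by fixed fractions (Winter-style
# proportions); inertial parameters come from published anthropometric
# fraction tables shipped as plain-text data files.

# Stature fractions used to size the planar chain.
SEGMENT_LENGTH_FRACTIONS <- c(
  thigh        = 0.245,
  shank        = 0.246,
  foot         = 0.152,  # heel to toe tip
  ankle_height = 0.039,
  pelvis_depth = 0.100,  # anterior-posterior pelvis marker separation
  pelvis_up    = 0.050,  # hip joint to pelvis-marker centroid
  hat_up       = 0.170   # pelvis centroid to head-arms-trunk CoM
)

#' Describe a subject
#'
#' Builds the subject record used throughout the pipeline: body mass, stature
#' and planar segment lengths derived from stature by fixed fractions.
#'
#' @param mass body mass in kg (> 0)
#' @param height stature in m (> 0)
#' @return an object of class `subject_spec`
#' @examples
#' subject_spec(78.9, 1.811)
#' @export
subject_spec <- function(mass = 78.9, height = 1.811) {
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0)
    stop("subject mass must be a single positive number")
  if (!is.numeric(height) || length(height) != 1 || !is.finite(height) || height <= 0)
    stop("subject height must be a single positive number")
  lens <- as.list(SEGMENT_LENGTH_FRACTIONS * height)
  structure(
    list(mass = mass, height = height, segment_lengths = lens),
    class = "subject_spec"
  )
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec> mass %.1f kg, height %.3f m\n", x$mass, x$height))
  invisible(x)
}

anthropometric_table <- function(table) {
  valid <- c("deleva1996", "dempster1955")
  if (length(table) != 1 || !table %in% valid)
    stop("unknown anthropometric table '", paste(table, collapse = ","),
         "'; available: ", paste(valid, collapse = ", "))
  path <- system.file("extdata", paste0("anthropometry_", table, ".tsv"),
                      package = "dvjmech")
  if (path == "") stop("anthropometric table file not found: ", table)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  total <- 2 * sum(tab$mass_fraction[tab$segment != "head_arms_trunk"]) +
    tab$mass_fraction[tab$segment == "head_arms_trunk"]
  if (abs(total - 1) > 1e-3)
    stop("mass fractions in table '", table, "' do not sum to 1 (got ",
         round(total, 4), ")")
  tab
}

#' Build the planar link-segment inertial model
#'
#' Per-segment mass, centre-of-mass location and moment of inertia for the
#' planar chain (foot, shank, thigh, head-arms-trunk remainder), from a
#' published anthropometric fraction table and the subject's mass and
#' segment lengths. Fractions are per single segment; paired segments (two
#' feet, shanks, thighs) plus the head-arms-trunk remainder account for the
#' whole body mass.
#'
#' @param subject a [subject_spec()]
#' @param table anthropometric table id, `"deleva1996"` (default) or
#'   `"dempster1955"`
#' @return an object of class `body_model` with a `segments` data frame
#'   (mass kg, length m, com_fraction from the proximal end,
#'   gyration_fraction, inertia kg m^2 about the segment CoM)
#' @examples
#' build_body_model(subject_spec(78.9, 1.811))
#' @export
build_body_model <- function(subject, table = "deleva1996") {
  stopifnot(inherits(subject, "subject_spec"))
  tab <- anthropometric_table(table)
  seg_len <- c(
    foot = subject$segment_lengths$foot,
    shank = subject$segment_lengths$shank,
    thigh = subject$segment_lengths$thigh,
    head_arms_trunk = NA_real_
  )
  tab$length <- unname(seg_len[tab$segment])
  tab$mass <- tab$mass_fraction * subject$mass
  tab$inertia <- ifelse(
    is.na(tab$length), NA_real_,
    tab$mass * (tab$gyration_fraction * tab$length)^2
  )
  structure(list(table = table, segments = tab, subject = subject),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> table %s, subject mass %.1f kg\n",
              x$table, x$subject$mass))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

model_segment <- function(model, name) {
  i <- match(name, model$segments$segment)
  if (is.na(i)) stop("unknown segment: ", name)
  as.list(model$segments[i, ])
}
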