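#' Define an obstacle with its rewarded clearance range
#'
#' An obstacle is characterized by its height class, its physical height, and
#' a closed "success range" of foot clearances `[h_lower, h_upper]` (distances
#' above the obstacle top, in meters) that are rewarded during practice.
#'
#' @param height_class `"LOW"` or `"HIGH"`.
#' @param physical_height Obstacle height in meters (must be positive).
#' @param h_lower,h_upper Success-range thresholds in meters, `0 <= h_lower <
#'   h_upper`.
#' @return A one-row `data.frame` with class `obstacle_spec`.
#' @examples
#' obstacle_spec("LOW", 0.05, 0.05, 0.09)
#' @export
obstacle_spec <- function(height_class, physical_height, h_lower, h_upper) {
  height_class <- match.arg(height_class, HEIGHT_CLASSES)
  stopifnot(is.numeric(physical_height), physical_height > 0,
            is.numeric(h_lower), is.numeric(h_upper),
            h_lower >= 0, h_lower < h_upper)
  out <- data.frame(height_class = height_class,
                    physical_height = physical_height,
                    h_lower = h_lower, h_upper = h_upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("obstacle_spec", class(out))
  out
}

#' Default obstacle definitions
#'
#' Two obstacle heights: LOW (0.05 m tall, success range 0.05--0.09 m above
#' the obstacle top) and HIGH (0.18 m tall, success range 0.01--0.05 m).
#'
#' @return A two-row `data.frame` (one `obstacle_spec` per height class).
#' @export
default_obstacle_specs <- function() {
  rbind(obstacle_spec("LOW", 0.05, 0.05, 0.09),
        obstacle_spec("HIGH", 0.18, 0.01, 0.05))
}

# Internal: fetch the row for a height class, with validation.
spec_for_class <- function(specs, height_class) {
  i <- match(height_class, specs$height_class)
  if (anyNA(i)) {
    stop("unknown height_class: ",
         paste(unique(height_class[is.na(i)]), collapse = ", "))
  }
  specs[i, , drop = FALSE]
}

# Internal: validate a specs table (one row per class, LOW and HIGH present).
check_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("height_class", "h_lower", "h_upper") %in% names(specs)))
  if (anyDuplicated(specs$height_class))
    stop("duplicate height_class in obstacle specs")
  if (any(specs$h_lower >= specs$h_upper))
    stop("h_lower must be < h_upper")
  invisible(specs)
}
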