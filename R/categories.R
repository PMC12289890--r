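#' Mark categories
#'
#' Volunteers classify each point mark into one of four categories: adult
#' males, "other" iguanas (females, sub-adults, juveniles), leks (breeding
#' aggregations) and partial iguanas (animals bisected by the tile edge,
#' marked separately so they are not double counted across tiles).
#'
#' @format Character vectors.
#' @name mark_categories
NULL

#' @rdname mark_categories
#' @export
MARK_CATEGORIES <- c("adult_male", "other", "lek", "partial")

#' @rdname mark_categories
#' @export
COUNTABLE_CATEGORIES <- c("adult_male", "other", "lek")

#' Abundance category of an expert count
#'
#' Images are binned by the expert count: `absent` (0), `low` (1-5),
#' `medium` (6-10) and `high` (>10 animals).
#'
#' @param count Vector of non-negative integer counts.
#' @return Factor with levels `absent`, `low`, `medium`, `high`.
#' @examples
#' abundance_category(c(0, 3, 5, 6, 10, 11, 35))
#' @export
abundance_category <- function(count) {
  if (any(count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  cut(count, breaks = c(-Inf, 0, 5, 10, Inf),
      labels = c("absent", "low", "medium", "high"))
}

# internal: deterministic half-up rounding used when integer counts are needed
round_half_up <- function(x) floor(x + 0.5)

# internal: natural ordering of classification ids ("10" after "9" when all
# ids are numeric; plain lexicographic otherwise)
order_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}
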