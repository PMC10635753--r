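#' Per-area observed and expected counts
#'
#' A `count_data` object pairs observed case counts O_i with internally
#' standardized expected counts E_i, the basis of the raw standardized
#' incidence/mortality ratio O_i / E_i and of the Poisson likelihood of the
#' smoothing model. Areas whose expected value had to be imputed (no
#' population at risk) carry an `uninformative` flag.
#'
#' @param area_id character vector of area codes.
#' @param observed non-negative integer counts.
#' @param expected positive expected counts.
#' @param uninformative logical flags for imputed expecteds.
#' @return object of class `count_data`.
#' @export
count_data <- function(area_id, observed, expected,
                       uninformative = rep(FALSE, length(area_id))) {
  area_id <- as.character(area_id)
  n <- length(area_id)
  stopifnot(length(observed) == n, length(expected) == n,
            length(uninformative) == n)
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  if (any(expected <= 0)) stop("all expected counts must be positive")
  structure(
    list(area_id = area_id, observed = as.integer(round(observed)),
         expected = as.numeric(expected),
         uninformative = as.logical(uninformative)),
    class = "count_data"
  )
}

#' @export
print.count_data <- function(x, ...) {
  cat("count_data:", length(x$area_id), "areas, total observed =",
      sum(x$observed), "\n")
  if (any(x$uninformative)) {
    cat("  uninformative expecteds:", sum(x$uninformative), "areas\n")
  }
  invisible(x)
}

#' Expected counts by internal standardization
#'
#' The overall rate r = sum(O) / sum(population over populated areas) is
#' applied to each area's population at risk (persons aged 15+):
#' E_i = r * pop_i. Areas with no resident population receive an
#' uninformative expected value r * 1 (the overall rate applied to a
#' notional population of one person), keeping E_i > 0 so the Poisson model
#' stays defined while injecting essentially no information; these areas
#' are flagged and excluded from the conservation identity
#' sum(E over populated areas) = sum(O).
#'
#' @param observed per-area non-negative counts.
#' @param population per-area population aged 15+ (zero allowed).
#' @param area_id optional area codes (taken from names of `observed` if
#'   absent).
#' @return a [count_data()] object.
#' @export
compute_expected <- function(observed, population, area_id = NULL) {
  if (is.null(area_id)) {
    area_id <- names(observed) %||% as.character(seq_along(observed))
  }
  n <- length(observed)
  stopifnot(length(population) == n)
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (any(population < 0)) stop("populations must be non-negative")
  populated <- population > 0
  if (!any(populated)) stop("all areas have zero population")
  rate <- sum(observed) / sum(population[populated])
  if (rate == 0) stop("no observed cases; expected counts would all be zero")
  expected <- ifelse(populated, rate * population, rate * 1)
  count_data(area_id, observed, expected, uninformative = !populated)
}

#' Raw standardized incidence / mortality ratio
#'
#' @param counts a [count_data()] object.
#' @return named numeric vector O_i / E_i; 1.00 is the state average.
#' @export
raw_ratio <- function(counts) {
  stopifnot(inherits(counts, "count_data"))
  stats::setNames(counts$observed / counts$expected, counts$area_id)
}

#' Write a count_data table as CSV
#'
#' @param counts a [count_data()] object.
#' @param path output path.
#' @export
write_count_data <- function(counts, path) {
  stopifnot(inherits(counts, "count_data"))
  utils::write.csv(
    data.frame(area_id = counts$area_id, observed = counts$observed,
               expected = counts$expected, raw_ratio = raw_ratio(counts),
               uninformative_flag = counts$uninformative,
               row.names = NULL),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a population-at-risk table
#'
#' CSV with columns `area_id, population_15plus`.
#'
#' @param path file path.
#' @return named integer vector of populations.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("area_id", "population_15plus") %in% names(df))) {
    stop("population table needs columns area_id, population_15plus")
  }
  stats::setNames(as.integer(df$population_15plus), as.character(df$area_id))
}
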