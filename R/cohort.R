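#' Default anatomical subsite dictionary
#'
#' Maps anatomical subsite labels to the two tumor-site classes used in
#' oral-cancer epidemiology: cancers of the anterior tongue, floor of the
#' mouth, buccal or labial mucosa, gingiva, hard palate and retromolar area
#' form the oral cavity class, while the tongue base, lingual and palatal
#' tonsils, soft palate and oropharyngeal walls form the oropharynx class.
#' Matching is case-insensitive; the dictionary is user-extensible.
#'
#' @return named character vector: names are subsite labels, values are
#'   `"oral_cavity"` or `"oropharynx"`.
#' @export
default_subsite_dictionary <- function() {
  c(
    "anterior tongue"    = "oral_cavity",
    "floor of the mouth" = "oral_cavity",
    "buccal mucosa"      = "oral_cavity",
    "labial mucosa"      = "oral_cavity",
    "gingiva"            = "oral_cavity",
    "hard palate"        = "oral_cavity",
    "retromolar area"    = "oral_cavity",
    "tongue base"        = "oropharynx",
    "lingual tonsil"     = "oropharynx",
    "palatal tonsil"     = "oropharynx",
    "soft palate"        = "oropharynx",
    "oropharyngeal wall" = "oropharynx"
  )
}

#' Classify a tumor subsite label
#'
#' @param subsite character vector of subsite labels.
#' @param dictionary named vector mapping labels to classes; see
#'   [default_subsite_dictionary()].
#' @return character vector with values `"oral_cavity"`, `"oropharynx"` or
#'   `"not_specified"` (unmapped labels).
#' @export
classify_site <- function(subsite, dictionary = default_subsite_dictionary()) {
  cls <- unname(dictionary[tolower(trimws(as.character(subsite)))])
  unmapped <- is.na(cls)
  if (any(unmapped)) {
    cls[unmapped] <- "not_specified"
    labs <- unique(subsite[unmapped])
    message("unmapped subsite label(s) -> not_specified: ",
            paste(utils::head(labs, 5), collapse = ", "),
            if (length(labs) > 5) ", ...")
  }
  cls
}

#' Read registry-style patient records
#'
#' Expects a delimited file with header columns `patient_id, age, sex,
#' subsite, area_id, vital_status, survival_months` (an optional `grade`
#' column is carried through as an opaque category).
#'
#' @param path CSV file path.
#' @return data frame of registry records with validated columns.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(df)
}

#' @keywords internal
validate_registry <- function(df) {
  req <- c("patient_id", "age", "sex", "subsite", "area_id", "vital_status",
           "survival_months")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("registry lacks column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$sex <- tolower(as.character(df$sex))
  df$vital_status <- tolower(as.character(df$vital_status))
  if (!all(df$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!all(df$vital_status %in% c("alive", "dead"))) {
    stop("vital_status must be 'alive' or 'dead'")
  }
  if (any(is.na(df$age)) || any(df$age < 0)) stop("age must be >= 0")
  bad <- df$vital_status == "dead" &
    (is.na(df$survival_months) | df$survival_months < 0)
  if (any(bad)) {
    stop("dead record(s) with missing survival_months: ",
         paste(df$patient_id[bad], collapse = ", "))
  }
  if (any(df$survival_months < 0, na.rm = TRUE)) {
    stop("survival_months must be >= 0")
  }
  df
}

#' Apply the minimum-age inclusion rule
#'
#' Registry analyses of adult oral cancer restrict to patients aged 15 and
#' over at diagnosis; the threshold is inclusive (age 15 is retained).
#' Excluded records are kept with a reason tag rather than dropped.
#'
#' @param records registry data frame.
#' @param min_age inclusion threshold in years (default 15).
#' @return list with elements `included`, `excluded` (with an
#'   `exclusion_reason` column) and `n_excluded_under_age`.
#' @export
apply_age_exclusion <- function(records, min_age = 15) {
  records <- validate_registry(records)
  keep <- records$age >= min_age
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$exclusion_reason <- paste0("age_under_", min_age)
  }
  list(included = records[keep, , drop = FALSE],
       excluded = excluded,
       n_excluded_under_age = sum(!keep))
}

#' Cohort descriptive summary
#'
#' Tabulates the included cohort by age band (<40, 40-64, >=65 years), sex,
#' tumor-site class, optional grade, and vital status. Percentages are on
#' the included total, rounded half-up to one decimal as printed in
#' registry descriptive tables.
#'
#' @param records age-filtered registry data frame.
#' @param dictionary subsite dictionary for [classify_site()].
#' @return object of class `cohort_summary`: a list of data frames
#'   (`age`, `sex`, `site`, `grade` if present, `status`), each with
#'   `category`, `n`, `pct`, plus `n_included`.
#' @export
cohort_summary <- function(records, dictionary = default_subsite_dictionary()) {
  records <- validate_registry(records)
  n <- nrow(records)
  if (n == 0) stop("empty cohort")
  tab <- function(x, levels) {
    cnt <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(category = levels, n = unname(cnt),
               pct = round_half_up(100 * unname(cnt) / n, 1),
               stringsAsFactors = FALSE)
  }
  age_band <- cut(records$age, breaks = c(-Inf, 39, 64, Inf),
                  labels = c("<40", "40-64", ">=65"))
  out <- list(
    n_included = n,
    age    = tab(as.character(age_band), c("<40", "40-64", ">=65")),
    sex    = tab(records$sex, c("female", "male")),
    site   = tab(classify_site(records$subsite, dictionary),
                 c("oral_cavity", "oropharynx", "not_specified")),
    status = tab(records$vital_status, c("alive", "dead"))
  )
  if (!is.null(records$grade)) {
    out$grade <- tab(as.character(records$grade),
                     sort(unique(as.character(records$grade))))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort summary: n =", x$n_included, "\n")
  for (blk in setdiff(names(x), "n_included")) {
    cat("--", blk, "--\n")
    df <- x[[blk]]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-24s %7d (%.1f)\n", df$category[i], df$n[i], df$pct[i]))
    }
  }
  invisible(x)
}

#' Write a cohort summary as CSV
#'
#' @param x a [cohort_summary()] object.
#' @param path output path.
#' @export
write_cohort_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  blocks <- setdiff(names(x), "n_included")
  df <- do.call(rbind, lapply(blocks, function(b) {
    cbind(variable = b, x[[b]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mortality strata by time from diagnosis
#'
#' Partitions deaths by survival time: within 3 years (<= 36 months),
#' between 3 and 5 years (37-60 months), and after 5 years (> 60 months).
#' Month thresholds operationalize "within 3/5 years" because registries
#' record survival at month granularity.
#'
#' @param records age-filtered registry data frame.
#' @return list with `deaths_within_36mo`, `deaths_37_to_60mo`,
#'   `deaths_after_60mo`, `total_deaths` (the strata sum exactly to the
#'   total).
#' @export
mortality_strata <- function(records) {
  records <- validate_registry(records)
  dead <- records[records$vital_status == "dead", , drop = FALSE]
  sm <- dead$survival_months
  list(
    deaths_within_36mo = sum(sm <= 36),
    deaths_37_to_60mo  = sum(sm >= 37 & sm <= 60),
    deaths_after_60mo  = sum(sm > 60),
    total_deaths       = nrow(dead)
  )
}

#' Aggregate registry records to per-area observed counts
#'
#' Bridges patient-level rows to the per-area counts the mapping model
#' consumes. Strata: `incidence` (all records), `overall_death` (deaths),
#' `death_within_36mo` and `death_within_60mo` (deaths by survival cutoff).
#'
#' @param records age-filtered registry data frame.
#' @param areas an [area_set()] (or character vector of area ids) defining
#'   the geography and count order.
#' @param stratum one of `"incidence"`, `"overall_death"`,
#'   `"death_within_36mo"`, `"death_within_60mo"`.
#' @return named integer vector of observed counts in area order.
#' @export
aggregate_counts <- function(records, areas,
                             stratum = c("incidence", "overall_death",
                                         "death_within_36mo",
                                         "death_within_60mo")) {
  stratum <- match.arg(stratum)
  records <- validate_registry(records)
  ids <- if (inherits(areas, "area_set")) areas$area_id else as.character(areas)
  unknown <- setdiff(unique(records$area_id), ids)
  if (length(unknown)) {
    stop("record(s) with unknown area_id: ", paste(unknown, collapse = ", "))
  }
  keep <- switch(stratum,
    incidence         = rep(TRUE, nrow(records)),
    overall_death     = records$vital_status == "dead",
    death_within_36mo = records$vital_status == "dead" & records$survival_months <= 36,
    death_within_60mo = records$vital_status == "dead" & records$survival_months <= 60
  )
  sub <- records[keep, , drop = FALSE]
  cnt <- table(factor(sub$area_id, levels = ids))
  stats::setNames(as.integer(cnt), ids)
}
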