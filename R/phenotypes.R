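#' Fat and protein content from lactation yields
#'
#' Content (%) = 100 * yield (kg) / milk yield (kg), per lactation record.
#'
#' @param records Lactation-record tibble with `milk_kg`, `fat_kg`,
#'   `protein_kg` columns.
#' @return `records` with `fat_pct` and `protein_pct` columns added.
#' @export
derive_contents <- function(records) {
  if (any(records$milk_kg <= 0, na.rm = TRUE)) {
    stop("undefined content: milk_kg must be > 0")
  }
  records |>
    dplyr::mutate(fat_pct = 100 * .data$fat_kg / .data$milk_kg,
                  protein_pct = 100 * .data$protein_kg / .data$milk_kg)
}

#' Keep only full lactations
#'
#' A 305-day record is considered a full lactation when the cow was milked for
#' at least `dim_min` days (default 270).
#'
#' @param records Lactation-record tibble with a `dim` (days in milk) column.
#' @param dim_min Minimum days in milk, inclusive.
#' @return Filtered tibble.
#' @export
filter_full_lactation <- function(records, dim_min = 270) {
  dplyr::filter(records, .data$dim >= dim_min)
}

#' Remove trait outliers beyond mean +/- k SD
#'
#' Mean and SD are computed once on the non-missing input values (single
#' pass); values strictly outside `mean +/- sd_mult * SD` are set to `NA`.
#' Values exactly on the boundary are kept.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param sd_mult Number of standard deviations defining the fence.
#' @return `x` with outliers replaced by `NA`.
#' @export
filter_outliers <- function(x, sd_mult = 3) {
  ok <- !is.na(x)
  if (sum(ok) == 0) {
    warning("all values missing; outlier filter is a no-op")
    return(x)
  }
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (is.na(s) || s == 0) return(x)
  x[ok & abs(x - m) > sd_mult * s] <- NA
  x
}

#' Cohort filter: minimum herd-structure group sizes
#'
#' Iteratively removes cows belonging to any farm, sire or birth-year level
#' with fewer than `min_per_level` cows, repeating until a fixed point is
#' reached (removing a small sire family can push a farm below the threshold,
#' and so on).
#'
#' @param cows Tibble with one row per cow and the grouping columns.
#' @param min_per_level Minimum cows per level of each grouping column.
#' @param group_cols Character vector of grouping columns.
#' @return The retained cow rows.
#' @export
filter_cohort <- function(cows, min_per_level = 20,
                          group_cols = c("farm", "sire", "birth_year")) {
  stopifnot(all(group_cols %in% names(cows)))
  if (anyDuplicated(cows$cow_id)) stop("cows must have one row per cow_id")
  repeat {
    keep <- rep(TRUE, nrow(cows))
    for (g in group_cols) {
      cnt <- table(cows[[g]])
      keep <- keep & (cnt[as.character(cows[[g]])] >= min_per_level)
    }
    if (all(keep)) break
    cows <- cows[keep, , drop = FALSE]
    if (nrow(cows) == 0) {
      stop("cohort filter removed every cow; lower min_per_level")
    }
  }
  cows
}

#' Lactation mean
#'
#' The lactation mean (LAm) of a trait is the arithmetic mean of its three
#' single-lactation values, defined only when all three are present.
#'
#' @param la1,la2,la3 Numeric vectors of per-lactation trait values.
#' @return Numeric vector: the mean where all three are non-missing, else `NA`.
#' @export
lactation_mean <- function(la1, la2, la3) {
  out <- (la1 + la2 + la3) / 3
  out[is.na(la1) | is.na(la2) | is.na(la3)] <- NA
  out
}

#' Build the analysis-ready phenotype table
#'
#' Runs the full phenotype-preparation pipeline on raw lactation records:
#' cohort filter (farm/sire/birth-year minimum group sizes), full-lactation
#' filter (days in milk), content derivation, per trait-lactation outlier
#' removal (mean +/- `sd_mult` SD), and lactation means. Traits are milk, fat
#' and protein yield (kg) and fat and protein content (%); lactations LA1-LA3
#' plus their mean LAm.
#'
#' @param records Raw lactation-record tibble (one row per cow and lactation)
#'   with yields, `dim`, and the covariate columns `farm`, `sire`,
#'   `birth_year`, `birth_season`, `calving_year`, `calving_season`,
#'   `age_first_calving`.
#' @param min_per_level,dim_min,sd_mult Filter parameters (defaults 20, 270, 3).
#' @return A list of class `pheno_table`:
#'   * `values` — long tibble `(cow_id, trait, lactation, value)` with
#'     lactation in `LA1`, `LA2`, `LA3`, `LAm`;
#'   * `covariates` — per `(cow_id, lactation)` covariate tibble (for `LAm`
#'     the first-lactation calving covariates are carried);
#'   * `n_per_lactation` — cows with at least one trait value per lactation.
#' @export
build_phenotypes <- function(records, min_per_level = 20, dim_min = 270,
                             sd_mult = 3) {
  cows <- records |>
    dplyr::distinct(.data$cow_id, .data$farm, .data$sire, .data$birth_year)
  cohort <- filter_cohort(cows, min_per_level)
  recs <- records |>
    dplyr::filter(.data$cow_id %in% cohort$cow_id) |>
    filter_full_lactation(dim_min) |>
    derive_contents()

  traits <- c("milk_kg", "fat_kg", "protein_kg", "fat_pct", "protein_pct")
  long <- recs |>
    dplyr::select("cow_id", "lactation", dplyr::all_of(traits)) |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::group_by(.data$trait, .data$lactation) |>
    dplyr::mutate(value = filter_outliers(.data$value, sd_mult)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(lactation = paste0("LA", .data$lactation))

  wide <- tidyr::pivot_wider(long, names_from = "lactation", values_from = "value")
  for (la in c("LA1", "LA2", "LA3")) {
    if (!la %in% names(wide)) wide[[la]] <- NA_real_
  }
  lam <- wide |>
    dplyr::mutate(LAm = lactation_mean(.data$LA1, .data$LA2, .data$LA3)) |>
    dplyr::filter(!is.na(.data$LAm)) |>
    dplyr::select("cow_id", "trait", value = "LAm") |>
    dplyr::mutate(lactation = "LAm")

  values <- dplyr::bind_rows(long, lam) |>
    dplyr::arrange(.data$trait, .data$lactation, .data$cow_id)

  cov_la <- recs |>
    dplyr::select("cow_id", "lactation", "farm", "sire", "birth_year",
                  "birth_season", "calving_year", "calving_season",
                  "age_first_calving") |>
    dplyr::mutate(lactation = paste0("LA", .data$lactation))
  cov_lam <- cov_la |>
    dplyr::filter(.data$lactation == "LA1") |>
    dplyr::mutate(lactation = "LAm")
  covariates <- dplyr::bind_rows(cov_la, cov_lam)

  n_per <- values |>
    dplyr::group_by(.data$lactation) |>
    dplyr::summarise(n_cows = dplyr::n_distinct(.data$cow_id), .groups = "drop")

  structure(list(values = values, covariates = covariates,
                 n_per_lactation = n_per),
            class = "pheno_table")
}

#' @export
print.pheno_table <- function(x, ...) {
  cat("<pheno_table>\n")
  cat(sprintf("  %d trait values, %d cows\n", nrow(x$values),
              dplyr::n_distinct(x$values$cow_id)))
  print(x$n_per_lactation)
  invisible(x)
}
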