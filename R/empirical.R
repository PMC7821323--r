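# Empirical estimators from insecticide-efficacy trial site-years: per
# site-year yield loss, mean outbreak-year yield loss (hence q), outbreak
# frequency, CSV input/output, and a synthetic record generator for testing
# (the original 23-site-year trial set is not deposited).

.record_cols <- c("site", "year", "untreated_yield_kg_ha",
                  "best_treated_yield_kg_ha", "outbreak")

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.record_cols, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("site-year records lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(records$best_treated_yield_kg_ha <= 0)) {
    stop("best treated yield (H) must be positive in every site-year record",
         call. = FALSE)
  }
  if (any(records$untreated_yield_kg_ha < 0)) {
    stop("untreated yield (U) must be non-negative", call. = FALSE)
  }
  if (any(records$year < 1900 | records$year > 2100)) {
    stop("site-year records contain implausible years (expected 1900-2100)",
         call. = FALSE)
  }
  records$outbreak <- as.logical(records$outbreak)
  records
}

#' Per site-year yield loss from an insecticide-efficacy trial
#'
#' `100 - (U / H) * 100`, where U is the untreated-control yield and H the
#' yield of the best insecticide treatment (taken as the site-year's
#' attainable yield). Negative values — the untreated plot out-yielding the
#' treated ones — are reported, not clipped.
#'
#' @param records site-year `data.frame` with columns `site`, `year`,
#'   `untreated_yield_kg_ha`, `best_treated_yield_kg_ha`, `outbreak`.
#' @return numeric vector of yield-loss percentages, one per record.
#' @examples
#' rec <- data.frame(site = "NW", year = 2015, untreated_yield_kg_ha = 3000,
#'                   best_treated_yield_kg_ha = 3437, outbreak = TRUE)
#' site_year_yield_loss(rec)
#' @export
site_year_yield_loss <- function(records) {
  records <- validate_records(records)
  100 - (records$untreated_yield_kg_ha /
           records$best_treated_yield_kg_ha) * 100
}

#' Mean outbreak-year yield loss and retained fraction q
#'
#' Arithmetic mean of [site_year_yield_loss()] over outbreak site-years
#' (default) or all site-years, and the corresponding retained fraction
#' `q = 1 - mean/100`. In the Iowa trials this gave a 12.7% mean outbreak-year
#' loss (q = 0.873) for aphid-susceptible varieties.
#'
#' @param records site-year `data.frame`.
#' @param outbreak_only average over outbreak records only (default `TRUE`).
#' @return list with `mean_loss_pct`, `q`, and `n` (records used).
#' @export
mean_outbreak_yield_loss <- function(records, outbreak_only = TRUE) {
  records <- validate_records(records)
  if (isTRUE(outbreak_only)) {
    records <- records[records$outbreak, , drop = FALSE]
    if (nrow(records) == 0L) {
      stop("no outbreak site-years: cannot estimate outbreak-year yield loss",
           call. = FALSE)
    }
  } else if (nrow(records) == 0L) {
    stop("no site-year records supplied", call. = FALSE)
  }
  m <- mean(site_year_yield_loss(records))
  list(mean_loss_pct = m, q = 1 - m / 100, n = nrow(records))
}

#' Outbreak frequency across site-years
#'
#' Unweighted proportion of site-years whose pest population exceeded the
#' economic threshold before the cutoff crop stage. In the Iowa trials, 10 of
#' 23 site-years (43.5%).
#'
#' @param records site-year `data.frame`.
#' @return proportion in \[0, 1\].
#' @export
outbreak_frequency <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0L) {
    stop("no site-year records supplied", call. = FALSE)
  }
  mean(records$outbreak)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; sd = 0 degenerates to
# the mean.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate synthetic site-year trial records
#'
#' A stand-in for insecticide-efficacy trial data (the underlying Iowa trial
#' set is not publicly deposited): outbreak flags are Bernoulli with
#' `outbreak_rate`; outbreak-year losses are drawn from a normal with mean
#' `loss_mean` and sd `loss_sd` truncated to \[0, 60\]%; non-outbreak years
#' get small noise around zero loss. The best-treated yield H is drawn around
#' 3537 kg/ha and the untreated yield is derived as `U = H * (1 - loss/100)`.
#' Output is reproducible given `seed`, and the caller's RNG state is
#' restored on exit.
#'
#' @param n number of site-years (> 0).
#' @param outbreak_rate outbreak probability per site-year.
#' @param loss_mean,loss_sd outbreak-year yield-loss distribution (percent).
#' @param seed integer seed.
#' @return site-year `data.frame` (see [site_year_yield_loss()]).
#' @examples
#' rec <- generate_fixture_records(23, seed = 1)
#' outbreak_frequency(rec)
#' @export
generate_fixture_records <- function(n, outbreak_rate = 0.435,
                                     loss_mean = 12.7, loss_sd = 6,
                                     seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer", call. = FALSE)
  if (outbreak_rate < 0 || outbreak_rate > 1) {
    stop("outbreak_rate must lie in [0, 1]", call. = FALSE)
  }
  if (loss_mean < 0 || loss_mean > 100 || loss_sd < 0) {
    stop("loss_mean must lie in [0, 100] and loss_sd must be >= 0",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  outbreak <- stats::runif(n) < outbreak_rate
  loss <- numeric(n)
  loss[outbreak] <- .rtruncnorm(sum(outbreak), loss_mean, loss_sd, 0, 60)
  loss[!outbreak] <- stats::rnorm(sum(!outbreak), 0, 0.5)
  h <- pmax(stats::rnorm(n, 3537, 300), 500)
  sites <- c("northwest_farm", "northeast_farm", "johnson_farm")
  data.frame(
    site = rep_len(sites, n),
    year = 2000L + (seq_len(n) - 1L) %% 19L,
    untreated_yield_kg_ha = h * (1 - loss / 100),
    best_treated_yield_kg_ha = h,
    outbreak = outbreak,
    stringsAsFactors = FALSE
  )
}

#' Read site-year records from CSV
#'
#' Columns `site,year,untreated_yield_kg_ha,best_treated_yield_kg_ha,outbreak`
#' (outbreak coded 0/1), header mandatory, UTF-8, '.' decimal separator.
#'
#' @param path CSV file path.
#' @return site-year `data.frame` with logical `outbreak`.
#' @export
read_site_year_records <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("records file not found: '%s'", path), call. = FALSE)
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_records(rec)
}

#' Write site-year records to CSV
#'
#' Inverse of [read_site_year_records()] (outbreak written as 0/1).
#'
#' @param records site-year `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_year_records <- function(records, path) {
  records <- validate_records(records)
  records$outbreak <- as.integer(records$outbreak)
  utils::write.csv(records[, .record_cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
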