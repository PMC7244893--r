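# CSV interfaces. Two detection dialects are supported:
#  - long/daily: site_id, year, day_index, operating (0/1), detection (0/1)
#  - wide/occasion: site_id, year, occ_1..occ_J with blank cells = missing
# Covariates travel in three small files: per-site (site_id, elev_m,
# border_dist), per-site-year (site_id, year, snares), per-year (year, ban).

#' Read daily detection records and aggregate into occasions
#'
#' @param path CSV with columns `site_id, year, day_index, operating,
#'   detection`.
#' @param occasion_length days per occasion (default 5).
#' @return A [survey_data()].
#' @export
read_detections_daily <- function(path, occasion_length = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "day_index", "operating", "detection")
  if (!all(need %in% names(df)))
    stop("daily detection CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sites <- sort(unique(df$site_id))
  years <- sort(unique(df$year))
  occ_list <- list()
  max_occ <- 0L
  for (i in seq_along(sites)) for (k in seq_along(years)) {
    sub <- df[df$site_id == sites[i] & df$year == years[k], ]
    if (!nrow(sub)) { occ_list[[paste(i, k)]] <- integer(0); next }
    sub <- sub[order(sub$day_index), ]
    days <- max(sub$day_index)
    operating <- integer(days); detection <- integer(days)
    operating[sub$day_index] <- sub$operating
    detection[sub$day_index] <- sub$detection
    o <- aggregate_occasions(operating, detection, occasion_length)
    occ_list[[paste(i, k)]] <- o
    max_occ <- max(max_occ, length(o))
  }
  y <- array(NA_real_, c(length(sites), max_occ, length(years)))
  for (i in seq_along(sites)) for (k in seq_along(years)) {
    o <- occ_list[[paste(i, k)]]
    if (length(o)) y[i, seq_along(o), k] <- o
  }
  survey_data(y, site_ids = sites, year_labels = years)
}

#' Read an occasion-level (wide) detection CSV
#'
#' @param path CSV with columns `site_id, year, occ_1..occ_J`; blank = not
#'   sampled.
#' @return A [survey_data()].
#' @export
read_detections_wide <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occ_cols <- grep("^occ_", names(df), value = TRUE)
  if (!length(occ_cols) || !all(c("site_id", "year") %in% names(df)))
    stop("wide detection CSV needs site_id, year and occ_* columns",
         call. = FALSE)
  occ_cols <- occ_cols[order(as.integer(sub("^occ_", "", occ_cols)))]
  sites <- sort(unique(df$site_id))
  years <- sort(unique(df$year))
  y <- array(NA_real_, c(length(sites), length(occ_cols), length(years)))
  for (r in seq_len(nrow(df))) {
    i <- match(df$site_id[r], sites)
    k <- match(df$year[r], years)
    y[i, , k] <- as.numeric(df[r, occ_cols])
  }
  survey_data(y, site_ids = sites, year_labels = years)
}

#' Write a survey to the wide occasion-level CSV dialect
#' @param sd a [survey_data()].
#' @param path output CSV path.
#' @export
write_detections_wide <- function(sd, path) {
  rows <- expand.grid(site = seq_len(sd$n_sites), year = seq_len(sd$n_years))
  occ <- t(vapply(seq_len(nrow(rows)), function(r)
    sd$y[rows$site[r], , rows$year[r]], numeric(sd$n_occasions)))
  df <- data.frame(site_id = sd$site_ids[rows$site],
                   year = sd$year_labels[rows$year])
  colnames(occ) <- paste0("occ_", seq_len(sd$n_occasions))
  utils::write.csv(cbind(df, occ), path, row.names = FALSE, na = "")
}

#' Read the three covariate CSVs into a covariate set
#'
#' @param site_path CSV `site_id, elev_m, border_dist`.
#' @param snares_path CSV `site_id, year, snares` (or `NULL` for none).
#' @param ban_path CSV `year, ban` (or `NULL` for all-zero).
#' @param site_ids,year_labels ordering taken from the survey they accompany.
#' @return A [covariate_set()].
#' @export
read_covariates <- function(site_path, snares_path = NULL, ban_path = NULL,
                            site_ids, year_labels) {
  sdf <- utils::read.csv(site_path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "elev_m", "border_dist") %in% names(sdf)))
    stop("site covariate CSV needs site_id, elev_m, border_dist",
         call. = FALSE)
  idx <- match(site_ids, sdf$site_id)
  if (anyNA(idx)) stop("site covariate CSV is missing sites: ",
                       paste(site_ids[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  sdf <- sdf[idx, ]
  K <- length(year_labels)
  snares <- NULL
  if (!is.null(snares_path)) {
    ndf <- utils::read.csv(snares_path, stringsAsFactors = FALSE)
    snares <- matrix(NA_real_, length(site_ids), K)
    for (r in seq_len(nrow(ndf))) {
      i <- match(ndf$site_id[r], site_ids)
      k <- match(ndf$year[r], year_labels)
      if (!is.na(i) && !is.na(k)) snares[i, k] <- ndf$snares[r]
    }
    if (anyNA(snares)) stop("snare CSV does not cover every site-year",
                            call. = FALSE)
  }
  ban <- rep(0L, K)
  if (!is.null(ban_path)) {
    bdf <- utils::read.csv(ban_path, stringsAsFactors = FALSE)
    ban <- bdf$ban[match(year_labels, bdf$year)]
    if (anyNA(ban)) stop("ban CSV does not cover every year", call. = FALSE)
  }
  covariate_set(elev_m = sdf$elev_m, border_dist = sdf$border_dist,
                snares = snares, ban = ban, n_years = K)
}

#' Write a covariate set to the three CSV dialects
#' @param cv a [covariate_set()].
#' @param dir output directory.
#' @param site_ids,year_labels labels matching the survey.
#' @return Invisibly, the three file paths.
#' @export
write_covariates <- function(cv, dir, site_ids, year_labels) {
  p1 <- file.path(dir, "covariates_site.csv")
  p2 <- file.path(dir, "covariates_snares.csv")
  p3 <- file.path(dir, "covariates_ban.csv")
  utils::write.csv(data.frame(site_id = site_ids, elev_m = cv$elev_raw,
                              border_dist = cv$border_raw),
                   p1, row.names = FALSE)
  grid <- expand.grid(site = seq_along(site_ids),
                      year = seq_along(year_labels))
  utils::write.csv(data.frame(site_id = site_ids[grid$site],
                              year = year_labels[grid$year],
                              snares = cv$snares_raw[cbind(grid$site,
                                                           grid$year)]),
                   p2, row.names = FALSE)
  utils::write.csv(data.frame(year = year_labels, ban = cv$ban),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Write retained draws to a chains CSV
#' @param chains a `posterior_chains` object.
#' @param path output path (one row per retained draw: chain, iteration,
#'   then parameters).
#' @export
write_chains <- function(chains, path) {
  d <- chains$draws
  rows <- do.call(rbind, lapply(seq_len(dim(d)[1]), function(ch)
    data.frame(chain = ch, iteration = seq_len(dim(d)[2]),
               matrix(d[ch, , ], dim(d)[2], dim(d)[3],
                      dimnames = list(NULL, chains$param_names)))))
  utils::write.csv(rows, path, row.names = FALSE)
}
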