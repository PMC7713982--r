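# Sampling design: biological season windows, Voronoi site assignment, and
# stratified 1:1 availability sampling.

#' Biological season windows
#'
#' Breeding: 1 April - 31 May (plus all lek records regardless of date);
#' summer: 1 June - 31 August; winter: 15 November - 15 March. Dates outside
#' all windows map to `"none"`.
#'
#' @return named list of `c(start_monthday, end_monthday)` encoded as
#'   month * 100 + day
#' @export
season_windows <- function() {
  list(breeding = c(401L, 531L), summer = c(601L, 831L), winter = c(1115L, 315L))
}

#' Assign records to biological seasons
#'
#' Lek-source records are breeding-season used points regardless of date; VHF
#' records are mapped by the season windows with inclusive endpoints.
#'
#' @param date `Date` vector (or parseable `"YYYY-MM-DD"` strings)
#' @param source character vector, `"vhf"` or `"lek"`
#' @return character vector in `{"breeding", "summer", "winter", "none"}`
#' @export
assign_season <- function(date, source = "vhf") {
  d <- tryCatch(as.Date(date), error = function(e) rep(NA, length(date)))
  if (any(is.na(d))) stop2("assign_season: input error, unparseable date(s): %s",
                           paste(utils::head(date[is.na(d)], 3), collapse = ", "))
  md <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  out <- rep("none", length(d))
  out[md >= 401L & md <= 531L] <- "breeding"
  out[md >= 601L & md <= 831L] <- "summer"
  out[md >= 1115L | md <= 315L] <- "winter"
  out[rep_len(source, length(d)) == "lek"] <- "breeding"
  out
}

#' Stratum year of a record
#'
#' The winter window spans the calendar turn; a winter stratum is labeled by
#' the calendar year of the window's start, so a 5 January location belongs to
#' the winter of the preceding year. Other seasons use the calendar year.
#'
#' @param date `Date` vector
#' @param season season labels from [assign_season()]
#' @return integer vector of stratum years
#' @export
season_year <- function(date, season) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  md <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  winter_tail <- season == "winter" & md <= 315L
  y[winter_tail] <- y[winter_tail] - 1L
  y
}

#' Assign points to sites by nearest population centroid
#'
#' Nearest-centroid (Euclidean) labeling, which equals membership in the
#' centroid's Voronoi polygon. Equidistant ties go to the lowest centroid
#' index.
#'
#' @param points 2-column matrix (or data frame with `x`, `y`)
#' @param centroids 2-column matrix of site centroids, one row per site
#' @return integer vector of site indices (1-based)
#' @export
assign_site <- function(points, centroids) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1) stop2("assign_site: need at least one centroid")
  d2 <- outer(points[, 1], centroids[, 1], `-`)^2 +
    outer(points[, 2], centroids[, 2], `-`)^2
  apply(d2, 1, which.min) # which.min returns the first (lowest-index) minimum
}

#' Draw stratified available points
#'
#' For every (site, year, season) stratum among the used points, draws exactly
#' the stratum's number of used points uniformly at random within the site's
#' Voronoi polygon clipped to the study extent (by rejection from the extent
#' with nearest-centroid membership), so used and available totals match 1:1
#' overall and within every stratum.
#'
#' @param used data frame of used points with columns `x`, `y`, `site`
#'   (integer site index), `year`, `season`
#' @param centroids 2-column matrix of site centroids
#' @param extent `c(xmin, xmax, ymin, ymax)`
#' @param seed integer seed
#' @return data frame of available points with columns `x`, `y`, `site`,
#'   `year`, `season`, `source = "avail"`, `label = "available"`
#' @export
draw_available <- function(used, centroids, extent, seed = 1) {
  set.seed(derive_seed(seed, 4242))
  strata <- unique(used[, c("site", "year", "season")])
  strata <- strata[order(strata$site, strata$year, strata$season), , drop = FALSE]
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    n <- sum(used$site == st$site & used$year == st$year & used$season == st$season)
    got <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(got) < n) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop2("draw_available: sampling error, stratum site %s / year %s / season %s has (near-)degenerate area",
              st$site, st$year, st$season)
      }
      m <- max(200L, 4L * n)
      px <- stats::runif(m, extent[1], extent[2])
      py <- stats::runif(m, extent[3], extent[4])
      keep <- assign_site(cbind(px, py), centroids) == st$site
      got <- rbind(got, cbind(px[keep], py[keep]))
    }
    got <- got[seq_len(n), , drop = FALSE]
    out[[i]] <- data.frame(x = got[, 1], y = got[, 2], site = st$site,
                           year = st$year, season = st$season,
                           source = "avail", label = "available")
  }
  do.call(rbind, out)
}

#' Build the labeled use-availability table from raw locations
#'
#' Assigns seasons (dropping gap dates with a logged count), stratum years,
#' and Voronoi sites to the used locations, then draws matched available
#' points per stratum.
#'
#' @param locations data frame with `x`, `y`, `date`, `source`
#' @param centroids 2-column matrix of site centroids
#' @param extent study extent `c(xmin, xmax, ymin, ymax)`
#' @param seed integer seed for availability sampling
#' @return data frame with columns `x`, `y`, `site`, `year`, `cal_year`,
#'   `season`, `source`, `label`
#' @export
prepare_use_avail <- function(locations, centroids, extent, seed = 1) {
  season <- assign_season(locations$date, locations$source)
  dropped <- sum(season == "none")
  if (dropped > 0) {
    log_msg("sampling", "dropped %d location(s) outside season windows", dropped)
  }
  keep <- season != "none"
  loc <- locations[keep, , drop = FALSE]
  season <- season[keep]
  used <- data.frame(
    x = loc$x, y = loc$y,
    site = assign_site(cbind(loc$x, loc$y), centroids),
    year = season_year(loc$date, season),
    cal_year = as.integer(format(as.Date(loc$date), "%Y")),
    season = season,
    source = as.character(loc$source),
    label = "used"
  )
  avail <- draw_available(used, centroids, extent, seed)
  avail$cal_year <- avail$year
  out <- rbind(used, avail[, names(used)])
  out$label <- factor(out$label, levels = c("available", "used"))
  rownames(out) <- NULL
  out
}
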