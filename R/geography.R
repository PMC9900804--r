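#' Great-circle distance by the haversine formula
#'
#' d = 2 R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2))),
#' with the Earth radius defaulting to 6,371 km. Vectorized over inputs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees
#' @param radius sphere radius in km (default 6371)
#' @return distance in km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius = 6371) {
  stopifnot(radius > 0)
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  if (any(c(lon1, lon2) <= -180 | c(lon1, lon2) > 180)) {
    stop("longitude outside (-180, 180]")
  }
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Migration-waypoint configuration
#'
#' Five fixed waypoint cities (Istanbul, Cairo, Phnom Penh, Anadyr, Prince
#' Rupert) and a routing table giving, for each unordered region pair, the
#' ordered waypoints a migration-informed path passes through; same-region
#' pairs travel directly. The default routes follow the usual conventions -
#' Cairo for paths into or out of Africa, Istanbul for Europe, Phnom Penh
#' toward Oceania, Anadyr then Prince Rupert into the Americas (so
#' AMR to AFR runs Prince Rupert, Anadyr, Cairo) - and both the coordinates
#' (standard gazetteer values) and the table are plain config that callers
#' can override.
#'
#' @param waypoints named list of `c(lat, lon)` for the five cities
#' @param routes named list: `"REGA|REGB"` (alphabetical) -> character
#'   vector of waypoint names in travel order from REGA to REGB
#' @param earth_radius km (default 6371)
#' @return object of class `waypoint_config`
#' @export
waypoint_config <- function(waypoints = NULL, routes = NULL,
                            earth_radius = 6371) {
  default_wp <- list(
    Istanbul = c(41.0082, 28.9784),
    Cairo = c(30.0444, 31.2357),
    PhnomPenh = c(11.5564, 104.9282),
    Anadyr = c(64.7337, 177.4968),
    PrinceRupert = c(54.3150, -130.3208)
  )
  if (is.null(waypoints)) waypoints <- default_wp
  need <- names(default_wp)
  if (!all(need %in% names(waypoints))) {
    stop("waypoints must include: ", paste(need, collapse = ", "))
  }
  if (is.null(routes)) {
    routes <- list(
      "AFR|AMR" = c("Cairo", "Anadyr", "PrinceRupert"),
      "AFR|CSA" = "Cairo",
      "AFR|EAS" = "Cairo",
      "AFR|EUR" = c("Cairo", "Istanbul"),
      "AFR|MID" = "Cairo",
      "AFR|OCE" = c("Cairo", "PhnomPenh"),
      "AMR|CSA" = c("Anadyr", "PrinceRupert"),
      "AMR|EAS" = c("Anadyr", "PrinceRupert"),
      "AMR|EUR" = c("Anadyr", "PrinceRupert"),
      "AMR|MID" = c("Anadyr", "PrinceRupert"),
      "AMR|OCE" = c("PhnomPenh", "Anadyr", "PrinceRupert"),
      "CSA|EAS" = character(0),
      "CSA|EUR" = "Istanbul",
      "CSA|MID" = character(0),
      "CSA|OCE" = "PhnomPenh",
      "EAS|EUR" = "Istanbul",
      "EAS|MID" = character(0),
      "EAS|OCE" = "PhnomPenh",
      "EUR|MID" = "Istanbul",
      "EUR|OCE" = c("Istanbul", "PhnomPenh"),
      "MID|OCE" = "PhnomPenh"
    )
  }
  structure(list(waypoints = waypoints, routes = routes,
                 earth_radius = earth_radius),
            class = "waypoint_config")
}

#' Waypoint-routed geographic distance between two populations
#'
#' Sums haversine legs source -> waypoint_1 -> ... -> waypoint_m ->
#' destination, with the waypoint sequence looked up by the populations'
#' region pair. For the reversed pair the stored route is traversed
#' backwards, so the distance is symmetric; same-region pairs (and routes
#' with an empty waypoint list) reduce to the direct haversine distance.
#'
#' @param pop_a,pop_b population labels
#' @param metadata data.frame with population, region, latitude, longitude
#'   (one row per population, e.g. unique rows of `ds$samples`)
#' @param cfg waypoint_config
#' @param use_waypoints set FALSE for the direct distance
#' @return distance in km
#' @export
waypoint_distance <- function(pop_a, pop_b, metadata,
                              cfg = waypoint_config(),
                              use_waypoints = TRUE) {
  look <- function(p) {
    row <- metadata[match(p, metadata$population), ]
    if (is.na(row$latitude) || is.na(row$longitude)) {
      stop("no coordinates for population ", p)
    }
    row
  }
  a <- look(pop_a); b <- look(pop_b)
  direct <- haversine_km(a$latitude, a$longitude, b$latitude, b$longitude,
                         cfg$earth_radius)
  if (!use_waypoints || identical(a$region, b$region)) return(direct)
  key <- paste(sort(c(a$region, b$region)), collapse = "|")
  if (!key %in% names(cfg$routes)) {
    stop("no waypoint route configured for region pair ", key)
  }
  wp <- cfg$routes[[key]]
  if (length(wp) == 0) return(direct)
  if (a$region != sort(c(a$region, b$region))[1]) wp <- rev(wp)
  pts <- rbind(c(a$latitude, a$longitude),
               do.call(rbind, cfg$waypoints[wp]),
               c(b$latitude, b$longitude))
  sum(haversine_km(pts[-nrow(pts), 1], pts[-nrow(pts), 2],
                   pts[-1, 1], pts[-1, 2], cfg$earth_radius))
}

#' Population-pair geographic distance matrix
#'
#' @param metadata one row per population (population, region, latitude,
#'   longitude); duplicate population rows are collapsed to the first
#' @param cfg waypoint_config
#' @param use_waypoints route through migration waypoints (default TRUE)
#' @return symmetric matrix of distances in km
#' @export
geographic_distance_matrix <- function(metadata, cfg = waypoint_config(),
                                       use_waypoints = TRUE) {
  md <- metadata[!duplicated(metadata$population), , drop = FALSE]
  pops <- sort(md$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) {
    for (b in seq_along(pops)) {
      if (b <= a) next
      m[a, b] <- m[b, a] <- waypoint_distance(pops[a], pops[b], md, cfg,
                                              use_waypoints)
    }
  }
  m
}

#' Correlation between genetic divergence and geographic distance
#'
#' Pearson correlation (with its parametric two-sided p) over the
#' off-diagonal upper-triangle pairs, plus a Mantel test: the same statistic
#' under joint row+column permutations of one matrix, with one-sided
#' p = (1 + #\{r* >= r\}) / (1 + n_perm).
#'
#' @param fst fst_matrix or symmetric numeric matrix
#' @param dist symmetric numeric matrix in the same population order
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @return list: pearson_r, pearson_p, mantel_r, mantel_p, n_perm
#' @export
correlate_fst_geography <- function(fst, dist, n_perm = 999, seed = 1) {
  m <- if (inherits(fst, "fst_matrix")) fst$values else fst
  stopifnot(is.matrix(m), is.matrix(dist), all(dim(m) == dim(dist)))
  if (!is.null(rownames(m)) && !is.null(rownames(dist)) &&
      !identical(rownames(m), rownames(dist))) {
    stop("population order differs between matrices")
  }
  n <- nrow(m)
  if (n < 4) stop("need at least 4 populations")
  ut <- upper.tri(m)
  x <- m[ut]; y <- dist[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant matrix: correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  r_obs <- unname(ct$estimate)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    pp <- sample.int(n)
    r_perm <- stats::cor(m[pp, pp][ut], y)
    if (r_perm >= r_obs) hits <- hits + 1L
  }
  list(pearson_r = r_obs, pearson_p = ct$p.value,
       mantel_r = r_obs, mantel_p = (1 + hits) / (1 + n_perm),
       n_perm = n_perm)
}
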