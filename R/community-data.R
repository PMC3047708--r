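# Incidence tables and site geometry.

.checkCommunity <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm)) stop("community table must be a matrix")
  if (is.null(rownames(comm)) || is.null(colnames(comm)))
    stop("community matrix needs site rownames and species colnames")
  if (anyDuplicated(rownames(comm))) stop("duplicate site identifiers")
  if (anyDuplicated(colnames(comm))) stop("duplicate species identifiers")
  if (!ncol(comm)) stop("community table has no species columns")
  bad <- which(!(comm %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(comm))
    stop("non-binary incidence value ", comm[bad[1]], " at site '",
         rownames(comm)[i[1]], "', species '", colnames(comm)[i[2]], "'")
  }
  storage.mode(comm) <- "double"
  comm
}

#' Read a site-by-species incidence table
#'
#' CSV with the site identifier in the first column and one 0/1 column per
#' species. Non-binary cells and duplicate identifiers are rejected.
#'
#' @param file path to the CSV.
#' @return sites x species numeric 0/1 matrix with dimnames.
#' @export
readCommunity <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2) stop("community CSV needs a site column plus species columns")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  .checkCommunity(m)
}

#' Write a community matrix to CSV
#'
#' @param comm sites x species 0/1 matrix.
#' @param file output path.
#' @export
writeCommunity <- function(comm, file) {
  d <- data.frame(site = rownames(comm), comm, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
}

#' Read a site-geometry table
#'
#' CSV with header `site,x,y,area,scale,parent` (scale and parent optional):
#' coordinates in metres (projected), sampled area in m^2, an optional scale
#' label (e.g. the quadrat side), and an optional parent-quadrat identifier
#' for nested designs.
#'
#' @param file path to the CSV.
#' @return data.frame with columns site, x, y, area, scale, parent.
#' @export
readGeometry <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("site", "x", "y", "area")
  if (!all(need %in% names(d)))
    stop("geometry CSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$site)) stop("duplicate site identifiers in geometry")
  if (any(!is.finite(d$area)) || any(d$area <= 0))
    stop("all areas must be positive")
  if (is.null(d$scale)) d$scale <- NA_real_
  if (is.null(d$parent)) d$parent <- NA_character_
  d[c("site", "x", "y", "area", "scale", "parent")]
}

#' Sorensen similarity of two species sets
#'
#' 2 |A intersect B| / (|A| + |B|); the species-level counterpart of
#' [phyloSor()], and exactly equal to it on a star phylogeny.
#'
#' @param set1,set2 character vectors (non-empty).
#' @return similarity in [0, 1].
#' @export
sorensen <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  if (!length(set1) || !length(set2))
    stop("Sorensen similarity is undefined for an empty set")
  2 * length(intersect(set1, set2)) / (length(set1) + length(set2))
}

#' Pairwise Sorensen matrix for a community table
#'
#' @param comm sites x species 0/1 matrix.
#' @return symmetric matrix with unit diagonal.
#' @export
pairwiseSorensen <- function(comm) {
  comm <- .checkCommunity(comm)
  s <- rowSums(comm)
  if (any(s == 0)) stop("sites with zero richness: ",
                        paste(rownames(comm)[s == 0], collapse = ", "))
  shared <- tcrossprod(comm)
  2 * shared / outer(s, s, `+`)
}

#' Pairwise site distances
#'
#' Planar Euclidean distances on projected metre coordinates (the default,
#' matching within-region separations of tens of metres to ~170 km), or
#' great-circle (haversine) distances when coordinates are lon/lat degrees.
#'
#' @param geometry data.frame as from [readGeometry()].
#' @param method "euclidean" or "haversine".
#' @return symmetric distance matrix (metres) with site dimnames.
#' @export
pairwiseDistances <- function(geometry, method = c("euclidean", "haversine")) {
  method <- match.arg(method)
  if (method == "euclidean") {
    d <- as.matrix(stats::dist(cbind(geometry$x, geometry$y)))
  } else {
    r <- 6371000
    lon <- geometry$x * pi / 180; lat <- geometry$y * pi / 180
    dlat <- outer(lat, lat, `-`); dlon <- outer(lon, lon, `-`)
    a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
    d <- 2 * r * asin(pmin(sqrt(a), 1))
  }
  dimnames(d) <- list(geometry$site, geometry$site)
  d
}

#' Observed species-area points
#'
#' One (area, richness) point per site/scale combination, for fitting the
#' species-area relationship S = c A^z. Sites with zero richness are dropped
#' with a warning (they carry no information for the log-log fit).
#'
#' @param comm sites x species 0/1 matrix.
#' @param geometry data.frame with at least site and area columns.
#' @return data.frame with columns site, scale, area, S.
#' @export
observedSAR <- function(comm, geometry) {
  comm <- .checkCommunity(comm)
  i <- match(rownames(comm), geometry$site)
  if (anyNA(i)) stop("sites missing an area: ",
                     paste(rownames(comm)[is.na(i)], collapse = ", "))
  out <- data.frame(site = rownames(comm), scale = geometry$scale[i],
                    area = geometry$area[i], S = rowSums(comm))
  if (any(out$S == 0)) {
    warning("dropping ", sum(out$S == 0), " site(s) with zero richness")
    out <- out[out$S > 0, ]
  }
  rownames(out) <- NULL
  out
}

#' Observed distance-decay points
#'
#' One (distance, Sorensen similarity) pair per unordered site pair —
#' n(n-1)/2 pairs for n sites — optionally restricted to one sampling scale
#' (similarity analyses conventionally use the largest scale of a nested
#' design). Coincident sites (d = 0) are flagged and excluded with a warning,
#' since they cannot enter logarithmic fits.
#'
#' @param comm sites x species 0/1 matrix.
#' @param geometry data.frame as from [readGeometry()].
#' @param scaleFilter optional scale label; only sites at this scale are used.
#' @param method distance method, see [pairwiseDistances()].
#' @return data.frame with columns site1, site2, d, chiS.
#' @export
observedDistanceDecay <- function(comm, geometry, scaleFilter = NULL,
                                  method = "euclidean") {
  comm <- .checkCommunity(comm)
  if (!is.null(scaleFilter)) {
    keep <- geometry$site[!is.na(geometry$scale) & geometry$scale == scaleFilter]
    comm <- comm[rownames(comm) %in% keep, , drop = FALSE]
  }
  s <- rowSums(comm)
  if (any(s == 0)) {
    warning("dropping ", sum(s == 0), " site(s) with zero richness")
    comm <- comm[s > 0, , drop = FALSE]
  }
  if (nrow(comm) < 2) stop("need at least 2 sites at the chosen scale")
  geo <- geometry[match(rownames(comm), geometry$site), ]
  if (anyNA(geo$site)) stop("sites missing geometry")
  dm <- pairwiseDistances(geo, method)
  sm <- pairwiseSorensen(comm)
  idx <- which(lower.tri(dm), arr.ind = TRUE)
  out <- data.frame(site1 = rownames(dm)[idx[, 2]],
                    site2 = rownames(dm)[idx[, 1]],
                    d = dm[idx], chiS = sm[idx])
  if (any(out$d == 0)) {
    warning("excluding ", sum(out$d == 0), " coincident site pair(s) (d = 0)")
    out <- out[out$d > 0, ]
  }
  rownames(out) <- NULL
  out
}
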