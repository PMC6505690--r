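#' Count inflection points of a centerline
#'
#' Discrete Frenet analysis of a polyline after uniform arc-length
#' resampling. At each interior sample the turning angle between the
#' adjacent segments yields a discrete curvature and, where that
#' curvature is at least `eps`, a unit normal (the in-plane direction the
#' curve is turning towards). An inflection is counted whenever the
#' normal flips between consecutive normal-bearing samples, i.e.
#' |N[j+1] - N[j]|^2 > 1 (a rotation of more than 60 degrees). Samples
#' below the curvature floor carry no normal and cannot produce a flip,
#' which keeps near-straight stretches from contributing; endpoints are
#' excluded by construction. For planar curves this reproduces the sign
#' changes of the signed curvature; for a circular helix, whose normal
#' rotates smoothly, it returns 0.
#'
#' @param centerline n x 3 (or n x 2) matrix, mm.
#' @param n resampling resolution (default 100).
#' @param eps curvature floor in mm^-1 below which no normal is assigned.
#' @return integer inflection count (0 for collinear input).
#' @export
countInflections <- function(centerline, n = 100L, eps = 1e-4) {
  m <- .asPoints(centerline)
  if (nrow(m) < 2L) return(0L)
  r <- resampleUniform(m, max(as.integer(n), 4L))
  nr <- nrow(r)
  seg <- r[-1L, , drop = FALSE] - r[-nr, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  tang <- seg / len
  normals <- NULL
  for (i in seq_len(nr - 2L)) {
    d <- tang[i + 1L, ] - tang[i, ]
    nd <- sqrt(sum(d^2))
    theta <- 2 * asin(pmin(1, nd / 2))
    ds <- (len[i] + len[i + 1L]) / 2
    if (theta / ds < eps) next
    mhat <- tang[i, ] + tang[i + 1L, ]
    mhat <- mhat / sqrt(sum(mhat^2))
    nrm <- d - sum(d * mhat) * mhat
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-300) next
    normals <- rbind(normals, nrm / nn)
  }
  if (is.null(normals) || nrow(normals) < 2L) return(0L)
  dn <- normals[-1L, , drop = FALSE] - normals[-nrow(normals), , drop = FALSE]
  sum(rowSums(dn^2) > 1)
}

#' Rib centerline metrics
#'
#' Curved length L_C (arc length of the centerline), endpoint chord L_S,
#' inflection count N and the inflection count metric
#' ICM = N * L_C / L_S, the tortuosity measure used for vertebral ribs.
#' A perfectly smooth single curve (N = 0) has ICM = 0; ICM is invariant
#' under uniform scaling of the centerline.
#'
#' @param rib a [Rib-class] or a centerline matrix.
#' @param n resampling resolution for the inflection count.
#' @param eps curvature floor, see [countInflections()].
#' @return one-row data.frame: `L_C_mm`, `L_S_mm`, `N`, `ICM`.
#' @export
ribMetrics <- function(rib, n = 100L, eps = 1e-4) {
  if (is(rib, "Rib")) {
    if (!rib@present) stop("rib absent")
    m <- rib@centerline
  } else {
    m <- rib
  }
  m <- .asPoints(m)
  lc <- arcLength(m)
  ls <- chordLength(m)
  if (ls < 1e-6) stop("degenerate chord: rib endpoints coincide")
  nInf <- countInflections(m, n = n, eps = eps)
  data.frame(L_C_mm = lc, L_S_mm = ls, N = nInf, ICM = nInf * lc / ls)
}

.ribKey <- function(rib) paste0(rib@side, rib@index)

## minimum-distance based contact test between two centerlines: fraction
## of samples of a closer than `threshold` to any sample of b.
.ribContactFraction <- function(a, b, nSample = 60L) {
  ra <- resampleUniform(a, nSample)
  rb <- resampleUniform(b, nSample)
  d2 <- outer(rowSums(ra^2), rep(1, nSample)) +
    outer(rep(1, nSample), rowSums(rb^2)) - 2 * ra %*% t(rb)
  dmin <- sqrt(pmax(0, apply(d2, 1L, min)))
  dmin
}

#' Rib presence and fusion census of a specimen
#'
#' Presence flags for every planned rib, a specimen-level flag for
#' "has at least one absent rib", and the list of fused rib pairs. A rib
#' pair is called fused when annotated (`fusedWith`) or when adjacent
#' same-side centerlines stay within `contactThreshold` of each other
#' over at least `contactFraction` of their samples.
#'
#' @param specimen a [Specimen-class].
#' @param contactThreshold contact distance in mm (default 0.05).
#' @param contactFraction minimum fraction of samples in contact
#'   (default 0.1).
#' @return list with `presence` (data.frame side, index, present),
#'   `hasAbsent` (logical) and `fusedPairs` (character two-column matrix,
#'   possibly empty).
#' @export
ribCensus <- function(specimen, contactThreshold = 0.05, contactFraction = 0.1) {
  stopifnot(is(specimen, "Specimen"))
  rr <- specimen@ribs
  presence <- data.frame(
    side = vapply(rr, slot, character(1), name = "side"),
    index = vapply(rr, slot, integer(1), name = "index"),
    present = vapply(rr, slot, logical(1), name = "present"),
    stringsAsFactors = FALSE)
  fusedPairs <- matrix(character(0), ncol = 2L)
  for (r in rr) {
    if (!is.na(r@fusedWith))
      fusedPairs <- rbind(fusedPairs, sort(c(.ribKey(r), r@fusedWith)))
  }
  for (side in c("left", "right")) {
    onSide <- Filter(function(r) r@side == side && r@present, rr)
    if (length(onSide) < 2L) next
    idx <- vapply(onSide, slot, integer(1), name = "index")
    onSide <- onSide[order(idx)]
    idx <- sort(idx)
    for (k in seq_len(length(onSide) - 1L)) {
      if (idx[k + 1L] != idx[k] + 1L) next
      dmin <- .ribContactFraction(onSide[[k]]@centerline, onSide[[k + 1L]]@centerline)
      if (mean(dmin < contactThreshold) >= contactFraction)
        fusedPairs <- rbind(fusedPairs,
                            sort(c(.ribKey(onSide[[k]]), .ribKey(onSide[[k + 1L]]))))
    }
  }
  if (nrow(fusedPairs)) fusedPairs <- unique(fusedPairs)
  list(presence = presence,
       hasAbsent = any(!presence$present),
       fusedPairs = fusedPairs)
}

#' Cohort summary of fifth-left-rib morphometry
#'
#' Mean and sample SD of the curved length and tortuosity (ICM) of the
#' fifth left vertebral rib across specimens of each (group, stage),
#' together with the proportion of specimens having at least one absent
#' rib. Specimens whose fifth left rib is absent are excluded from the
#' length/ICM means but still count towards the absence proportion.
#'
#' @param specimens list of [Specimen-class] objects.
#' @param side,index which rib to summarise (default fifth left).
#' @return data.frame with one row per (group, stage).
#' @export
cohortRibSummary <- function(specimens, side = "left", index = 5L) {
  if (is(specimens, "Specimen")) specimens <- list(specimens)
  if (!length(specimens)) stop("empty group")
  rows <- lapply(specimens, function(sp) {
    rib <- Filter(function(r) r@side == side && r@index == index, sp@ribs)
    met <- if (length(rib) && rib[[1L]]@present) ribMetrics(rib[[1L]]) else
      data.frame(L_C_mm = NA_real_, L_S_mm = NA_real_, N = NA_integer_,
                 ICM = NA_real_)
    cbind(data.frame(group = treatmentGroup(sp), stage = embryonicDay(sp),
                     has_absent = ribCensus(sp)$hasAbsent,
                     stringsAsFactors = FALSE), met)
  })
  tab <- do.call(rbind, rows)
  keys <- unique(tab[, c("group", "stage")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- tab[tab$group == keys$group[k] & tab$stage == keys$stage[k], ]
    ok <- !is.na(sub$L_C_mm)
    data.frame(group = keys$group[k], stage = keys$stage[k], n = nrow(sub),
               n_rib_measured = sum(ok),
               mean_L_C = if (any(ok)) mean(sub$L_C_mm[ok]) else NA_real_,
               sd_L_C = if (sum(ok) > 1) sd(sub$L_C_mm[ok]) else NA_real_,
               mean_ICM = if (any(ok)) mean(sub$ICM[ok]) else NA_real_,
               sd_ICM = if (sum(ok) > 1) sd(sub$ICM[ok]) else NA_real_,
               prop_absent = mean(sub$has_absent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean nearest-neighbour spacing between adjacent ribs
#'
#' Descriptive extension (not part of the core morphometry): for each
#' adjacent same-side pair of present ribs, the mean over samples of one
#' centerline of the distance to the nearest sample of the other,
#' averaged over pairs. Reported to let reduced inter-rib spacing be
#' tracked quantitatively.
#'
#' @param specimen a [Specimen-class].
#' @return mean spacing in mm, or `NA` when no adjacent pair exists.
#' @export
ribSpacingStat <- function(specimen) {
  stopifnot(is(specimen, "Specimen"))
  vals <- c()
  for (side in c("left", "right")) {
    onSide <- Filter(function(r) r@side == side && r@present, specimen@ribs)
    if (length(onSide) < 2L) next
    idx <- vapply(onSide, slot, integer(1), name = "index")
    onSide <- onSide[order(idx)]
    idx <- sort(idx)
    for (k in seq_len(length(onSide) - 1L)) {
      if (idx[k + 1L] != idx[k] + 1L) next
      vals <- c(vals, mean(.ribContactFraction(onSide[[k]]@centerline,
                                               onSide[[k + 1L]]@centerline)))
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}
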