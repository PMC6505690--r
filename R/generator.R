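## Synthetic chick-like specimen generator. Default configurations are
## calibrated so that the measurement pipeline recovers published cohort
## statistics for control and single-day-immobilised groups (Im3..Im6)
## across embryonic days E5-E9; see the methods vignette for the full
## parameter table and the reasoning behind invented values.

.vertLabels <- function(counts) {
  unlist(lapply(names(counts), function(r) paste0(r, seq_len(counts[[r]]))),
         use.names = FALSE)
}

## ordered so that successive prefixes spread over thoracic and lumbar
## regions first (where deformity concentrates), then cervical
.wedgeCandidates <- c("T2", "L2", "T5", "L5", "C10", "T3", "L1", "L6",
                      "C12", "T6", "L4", "C9", "T1", "L7")
.wedgeAngleTable <- c(15, 18, 14, 16, 20, 15, 13, 17, 19, 14, 16, 15, 18, 14)

.controlHeights <- c(`5` = 5.0, `6` = 6.2, `7` = 7.8, `8` = 9.4, `9` = 10.9)
.controlHeightSd <- c(`5` = 0.3, `6` = 0.4, `7` = 0.45, `8` = 0.55, `9` = 0.6)
.controlLc5 <- c(`5` = NA, `6` = 0.8, `7` = 1.5, `8` = 2.1, `9` = 2.7)
.controlLc5Sd <- c(`5` = NA, `6` = 0.1, `7` = 0.2, `8` = 0.3, `9` = 0.36)
.im4Lc5 <- c(`5` = NA, `6` = 0.7, `7` = 1.1, `8` = 1.9, `9` = 2.3)
.ribIndexScale <- c(0.65, 0.8, 0.9, 0.97, 1.0, 0.92, 0.8)

.mkDeformities <- function(label = character(0), amp = numeric(0),
                           width = numeric(0), sign = character(0)) {
  data.frame(label = label, amp = amp, width = width, sign = sign,
             stringsAsFactors = FALSE)
}

.mkWedgePlan <- function(k) {
  if (k < 1L) return(data.frame(label = character(0), angle_deg = numeric(0),
                                stringsAsFactors = FALSE))
  data.frame(label = .wedgeCandidates[seq_len(k)],
             angle_deg = .wedgeAngleTable[seq_len(k)], stringsAsFactors = FALSE)
}

.mkRibPlan <- function(present, lc5, wavAmp, wavLambda) {
  grid <- expand.grid(side = c("left", "right"), index = 1:7,
                      stringsAsFactors = FALSE)
  grid$present <- present
  grid$targetLc <- if (is.na(lc5)) NA_real_ else lc5 * .ribIndexScale[grid$index]
  grid$wavAmp <- wavAmp
  grid$wavLambda <- wavLambda
  grid
}

#' Calibrated generator configuration for a stage and group
#'
#' Returns the deterministic default [GeneratorConfig-class] for one
#' embryonic day (5-9) and treatment group. Control configurations have
#' empty deformity, wedge and fusion plans and all ribs present from E6;
#' immobilised configurations plant stage- and group-dependent curvature
#' deformities, wedge counts, fusions, rib shortening, rib waviness and
#' absent-rib assignments whose cohort statistics match the published
#' group values (e.g. control spine height 6.2 mm at E6 and 10.9 mm at
#' E9; fifth-left rib length 2.7 mm in E9 controls vs 1.7 mm after E5
#' immobilisation; 8 wedged vertebrae at E9 after E4 immobilisation;
#' absent ribs planted in 5 of every 6 specimens after E5
#' immobilisation).
#'
#' @param stage embryonic day, integer 5-9 (or a string like `"E9"`).
#' @param group `"control"`, `"Im3"`, `"Im4"`, `"Im5"` or `"Im6"`.
#' @return a [GeneratorConfig-class].
#' @examples
#' defaultConfig(9, "Im4")
#' @export
defaultConfig <- function(stage, group) {
  if (is.character(stage)) stage <- sub("^[Ee]", "", stage)
  stage <- as.integer(stage)
  if (is.na(stage) || !stage %in% 5:9) stop("unknown stage: must be 5..9")
  group <- as.character(group)
  if (!group %in% c("control", "Im3", "Im4", "Im5", "Im6"))
    stop("unknown group: ", group)
  st <- as.character(stage)

  height <- unname(.controlHeights[st])
  heightSd <- unname(.controlHeightSd[st])
  wedgeMean <- 0; wedgeSd <- 0
  fusionPlan <- character(0)
  deform <- .mkDeformities()
  lc5 <- unname(.controlLc5[st]); lc5Sd <- unname(.controlLc5Sd[st])
  wavAmp <- 0.004; wavLambda <- 0.8
  absentNum <- 0L; absentDen <- 1L; absentPer <- 1L

  ramp <- max(0, (stage - 5) / 4)  # severity ramp for groups observed at E9
  if (group == "Im4") {
    if (stage >= 8) height <- height * 0.9
    wedgeMean <- c(`5` = 0, `6` = 1, `7` = 2.8, `8` = 5.4, `9` = 8)[[st]]
    wedgeSd <- c(`5` = 0, `6` = 1, `7` = 1.8, `8` = 1.5, `9` = 1.2)[[st]]
    lc5 <- unname(.im4Lc5[st])
    wavAmp <- c(`5` = 0.004, `6` = 0.01, `7` = 0.06, `8` = 0.1, `9` = 0.02)[[st]]
    wavLambda <- c(`5` = 0.8, `6` = 0.8, `7` = 0.7, `8` = 0.5, `9` = 0.8)[[st]]
    deform <- switch(st,
      `5` = .mkDeformities("C6", 0.15, 1.5, "kyphotic"),
      `6` = .mkDeformities(c("L2", "T3"), c(0.25, 0.15), c(1.5, 1.5),
                           c("kyphotic", "lordotic")),
      `7` = .mkDeformities(c("C7", "L5"), c(0.25, 0.35), c(1.5, 1.5),
                           c("lordotic", "kyphotic")),
      `8` = .mkDeformities(c("C10", "T4", "L3"), c(0.35, 0.4, 0.45),
                           c(1.5, 1.5, 1.5),
                           c("kyphotic", "lordotic", "kyphotic")),
      `9` = .mkDeformities(c("C10", "T4", "L3", "L6"), c(0.4, 0.5, 0.5, 0.35),
                           c(1.5, 1.5, 1.5, 1.2),
                           c("kyphotic", "lordotic", "kyphotic", "lordotic")))
    if (stage == 7) { absentNum <- 4L; absentDen <- 5L; absentPer <- 2L }
    if (stage == 9) { absentNum <- 2L; absentDen <- 9L }
  } else if (group == "Im3") {
    wedgeMean <- 3 * ramp; wedgeSd <- if (stage == 9) 1 else 0.5
    if (stage == 9) {
      fusionPlan <- "C13"  # cervical pair, disjoint from wedge candidates
      deform <- .mkDeformities(c("L5", "C10"), c(0.45, 0.3), c(1.5, 1.5),
                               c("kyphotic", "lordotic"))
      lc5 <- 2.6; lc5Sd <- 0.3; wavAmp <- 0.01
      absentNum <- 1L; absentDen <- 7L
    }
  } else if (group == "Im5") {
    wedgeMean <- 3 * ramp; wedgeSd <- if (stage == 9) 1 else 0.5
    if (stage == 9) {
      deform <- .mkDeformities(c("C11", "L4"), c(0.3, 0.3), c(1.5, 1.5),
                               c("kyphotic", "lordotic"))
      lc5 <- 1.7; lc5Sd <- 0.22; wavAmp <- 0.01
      absentNum <- 5L; absentDen <- 6L; absentPer <- 2L
    }
  } else if (group == "Im6") {
    wedgeMean <- 2 * ramp; wedgeSd <- if (stage == 9) 1 else 0.5
    if (stage == 9) {
      lc5 <- 2.6; lc5Sd <- 0.3; wavAmp <- 0.008
      absentNum <- 1L; absentDen <- 6L
    }
  }

  new("GeneratorConfig",
      stage = stage, group = group,
      targetHeightMm = height, heightSd = heightSd,
      vertebraCounts = c(C = 14L, T = 7L, L = 7L),
      baselineAmp = 0.15 * height / 10.9,
      deformities = deform,
      wedgePlan = .mkWedgePlan(as.integer(round(wedgeMean))),
      wedgeMean = wedgeMean, wedgeSd = wedgeSd,
      fusionPlan = fusionPlan,
      ribPlan = .mkRibPlan(present = stage >= 6 && !is.na(lc5), lc5 = lc5,
                           wavAmp = wavAmp, wavLambda = wavLambda),
      ribLcSd = if (is.na(lc5Sd)) 0 else lc5Sd,
      absentNum = absentNum, absentDen = absentDen,
      absentPerSpecimen = absentPer,
      noiseSd = 0.005, seed = 1L)
}

#' Remove landmark noise from a configuration
#'
#' Convenience copy of a [GeneratorConfig-class] with the landmark noise
#' SD set to zero, so that planted quantities are recovered exactly.
#'
#' @param config a `GeneratorConfig`.
#' @return the modified configuration.
#' @export
noiseFree <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  config@noiseSd <- 0
  config
}

#' Generate a synthetic spine
#'
#' Lays vertebral centres along the configured baseline sagittal template
#' plus Gaussian-bump deformities, uniformly rescales so that the C8-L7
#' chord equals the target spine height exactly (before noise), builds
#' endplates perpendicular to the local tangent (rotating the superior
#' endplate by the planted angle for wedged vertebrae, and overlapping
#' endplates for planted fusions), and finally adds i.i.d. Gaussian
#' landmark noise. The same (config, seed) pair always returns an
#' identical spine.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer RNG seed (only noise consumes randomness).
#' @param id optional specimen id.
#' @return a [Spine-class].
#' @export
generateSpine <- function(config, seed = config@seed, id = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  set.seed(as.integer(seed))
  counts <- config@vertebraCounts
  labels <- .vertLabels(counts)
  n <- length(labels)
  u <- seq_len(n)
  delta <- config@targetHeightMm / 20  # nominal spacing: C8..L7 spans 20 gaps

  x <- config@baselineAmp * sin(2 * pi * (u - 1) / (n - 1))
  if (nrow(config@deformities)) {
    for (k in seq_len(nrow(config@deformities))) {
      d <- config@deformities[k, ]
      c0 <- match(d$label, labels)
      if (is.na(c0)) stop("invalid deformity location: ", d$label)
      sgn <- if (d$sign == "kyphotic") -1 else 1
      x <- x + sgn * d$amp * exp(-(u - c0)^2 / (2 * d$width^2))
    }
  }
  y <- -(u - 1) * delta
  centres <- cbind(x, y, 0)

  i8 <- match("C8", labels); i28 <- match("L7", labels)
  chord <- sqrt(sum((centres[i28, ] - centres[i8, ])^2))
  centres <- centres * config@targetHeightMm / chord

  seg <- sqrt(rowSums((centres[-1L, ] - centres[-n, ])^2))
  spacing <- mean(seg)
  half <- 0.35 * spacing   # endplate half-width
  off <- 0.35 * spacing    # endplate offset from centre along the axis

  tang <- rbind(centres[2L, ] - centres[1L, ],
                centres[3:n, ] - centres[1:(n - 2L), ],
                centres[n, ] - centres[n - 1L, ])
  tang <- .unitRows(tang)

  ## planted fusions: the inferior endplate of i and the superior
  ## endplate of i+1 are pushed past each other so the axial gap is
  ## negative (the geometric criterion fires) and the pair is annotated
  supOff <- rep(off, n); infOff <- rep(off, n)
  fusedNext <- rep(FALSE, n)
  fuseIdx <- match(config@fusionPlan, labels)
  if (length(fuseIdx) && (any(is.na(fuseIdx)) || any(fuseIdx >= n)))
    stop("invalid fusion location")
  infOff[fuseIdx] <- 0.55 * spacing
  supOff[fuseIdx + 1L] <- 0.55 * spacing
  fusedNext[fuseIdx] <- TRUE

  wedgeAngles <- rep(0, n)
  if (nrow(config@wedgePlan)) {
    wi <- match(config@wedgePlan$label, labels)
    if (any(is.na(wi))) stop("invalid wedge location")
    wedgeAngles[wi] <- config@wedgePlan$angle_deg
  }

  v <- data.frame(label = labels,
                  region = rep(names(counts), counts),
                  ord = u,
                  cx = centres[, 1], cy = centres[, 2], cz = centres[, 3],
                  sx1 = 0, sy1 = 0, sz1 = 0, sx2 = 0, sy2 = 0, sz2 = 0,
                  ix1 = 0, iy1 = 0, iz1 = 0, ix2 = 0, iy2 = 0, iz2 = 0,
                  fusedWithNext = fusedNext, stringsAsFactors = FALSE)
  for (i in u) {
    t <- tang[i, ]
    e <- c(-t[2], t[1], 0)
    e <- e / sqrt(sum(e^2))
    if (e[1] < 0) e <- -e  # anterior-pointing
    supMid <- centres[i, ] - supOff[i] * t
    infMid <- centres[i, ] + infOff[i] * t
    eSup <- e
    if (wedgeAngles[i] > 0) {
      th <- wedgeAngles[i] * pi / 180
      eSup <- c(e[1] * cos(th) - e[2] * sin(th),
                e[1] * sin(th) + e[2] * cos(th), 0)
    }
    v[i, c("sx1", "sy1", "sz1")] <- supMid - half * eSup
    v[i, c("sx2", "sy2", "sz2")] <- supMid + half * eSup
    v[i, c("ix1", "iy1", "iz1")] <- infMid - half * e
    v[i, c("ix2", "iy2", "iz2")] <- infMid + half * e
  }

  if (config@noiseSd > 0) {
    coordCols <- c("cx", "cy", "cz", "sx1", "sy1", "sz1", "sx2", "sy2", "sz2",
                   "ix1", "iy1", "iz1", "ix2", "iy2", "iz2")
    for (cc in coordCols)
      v[[cc]] <- v[[cc]] + rnorm(n, sd = config@noiseSd)
  }

  Spine(specimenID = id %||% sprintf("%s_E%d_seed%d", config@group,
                                     config@stage, as.integer(seed)),
        stage = config@stage, group = config@group, vertebrae = v,
        regionMap = counts)
}

#' Generate synthetic ribs for a spine
#'
#' Each planned-present rib is a 3D centerline launched laterally from
#' its thoracic vertebra: a circular arc bowing anteriorly with a gentle
#' caudal droop, plus sinusoidal waviness of the configured amplitude and
#' wavelength in the craniocaudal direction. The polyline is rescaled so
#' its arc length equals the planned curved length exactly.
#' Planned-absent ribs are returned with `present = FALSE`. Rib
#' centerlines are emitted smooth (no point-wise jitter): centerlines
#' extracted from segmented surfaces are smooth by construction, and
#' between-specimen rib variability enters through the planned lengths
#' and waviness instead.
#'
#' @param config a [GeneratorConfig-class].
#' @param spine the [Spine-class] the ribs attach to.
#' @param seed integer RNG seed.
#' @return list of [Rib-class] objects (one per rib plan row).
#' @export
generateRibs <- function(config, spine, seed = config@seed) {
  stopifnot(is(config, "GeneratorConfig"), is(spine, "Spine"))
  set.seed(as.integer(seed))
  v <- spine@vertebrae
  plan <- config@ribPlan
  out <- vector("list", nrow(plan))
  arcAngle <- 1.86  # total turning of the rib arc (rad): L_C/L_S ~ 1.15
  for (k in seq_len(nrow(plan))) {
    row <- plan[k, ]
    if (!isTRUE(row$present) || is.na(row$targetLc)) {
      out[[k]] <- Rib(row$side, row$index)
      next
    }
    iv <- match(paste0("T", row$index), v$label)
    if (is.na(iv)) {
      out[[k]] <- Rib(row$side, row$index)
      next
    }
    ctr <- c(v$cx[iv], v$cy[iv], v$cz[iv])
    lat <- if (row$side == "left") c(0, 0, 1) else c(0, 0, -1)
    ant <- c(1, 0, 0); cran <- c(0, 1, 0)
    L <- row$targetLc
    npts <- max(15L, as.integer(ceiling(L / min(0.15, row$wavLambda / 6))) + 1L)
    s <- seq(0, 1, length.out = npts)
    R <- L / arcAngle
    phi <- arcAngle * s
    wav <- row$wavAmp * sin(2 * pi * L * s / row$wavLambda)
    pts <- matrix(0, npts, 3L)
    for (j in seq_len(npts)) {
      pts[j, ] <- R * sin(phi[j]) * lat + R * (1 - cos(phi[j])) * ant +
        (-0.12 * L * s[j] + wav[j]) * cran
    }
    pts <- pts * (L / arcLength(pts))
    start <- ctr + 0.1 * lat
    pts <- pts + rep(1, npts) %o% start
    out[[k]] <- Rib(row$side, row$index, centerline = pts)
  }
  out
}

## centered, unit-SD jitter: cohort means of jittered quantities match
## their calibration target exactly (empirical second-moment matching)
.centeredJitter <- function(n) {
  if (n < 2L) return(rep(0, n))
  z <- rnorm(n)
  z <- z - mean(z)
  s <- sd(z)
  if (s < 1e-12) rep(0, n) else z / s
}

## integer count allocation: per-specimen counts with the configured
## spread whose cohort sum equals round(n * target)
.allocCounts <- function(target, sdev, z, cap) {
  n <- length(z)
  S <- min(round(n * target), n * cap)
  raw <- pmin(pmax(0, target + sdev * z), cap)
  counts <- floor(raw)
  rem <- raw - counts
  need <- S - sum(counts)
  if (need > 0) {
    ord <- order(rem, decreasing = TRUE)
    k <- 0L
    while (need > 0 && k < 4L * n) {
      j <- ord[(k %% n) + 1L]
      if (counts[j] < cap) { counts[j] <- counts[j] + 1L; need <- need - 1 }
      k <- k + 1L
    }
  } else if (need < 0) {
    ord <- order(rem)
    k <- 0L
    while (need < 0 && k < 4L * n) {
      j <- ord[(k %% n) + 1L]
      if (counts[j] > 0) { counts[j] <- counts[j] - 1L; need <- need + 1 }
      k <- k + 1L
    }
  }
  as.integer(counts)
}

#' Generate a synthetic cohort
#'
#' Generates `n` specimens from a configuration, with between-specimen
#' variability drawn around the calibration targets: spine heights and
#' fifth-left rib lengths receive centered Gaussian jitter with the
#' configured SDs (so cohort means sit on the targets), wedge counts are
#' drawn with the configured SD under the constraint that the cohort
#' total matches the target mean, wedged labels and angles are resampled
#' per specimen, and absent-rib specimens are assigned deterministically
#' in seed order (specimen i is affected iff
#' `((i-1) mod absentDen) < absentNum`). Specimen i uses seed
#' `baseSeed + i - 1`; the whole cohort is a pure function of
#' (config, n, baseSeed).
#'
#' @param config a [GeneratorConfig-class].
#' @param n cohort size (>= 1).
#' @param baseSeed integer base seed.
#' @return list of [Specimen-class] objects.
#' @export
generateCohort <- function(config, n, baseSeed = 1L) {
  stopifnot(is(config, "GeneratorConfig"), n >= 1)
  n <- as.integer(n)
  baseSeed <- as.integer(baseSeed)
  set.seed(baseSeed)
  zH <- .centeredJitter(n)
  zL <- .centeredJitter(n)
  counts <- .allocCounts(config@wedgeMean, config@wedgeSd, .centeredJitter(n),
                         cap = length(.wedgeCandidates))
  wedgePlans <- lapply(seq_len(n), function(i) {
    k <- counts[i]
    if (k < 1L) return(.mkWedgePlan(0L))
    labs <- sample(.wedgeCandidates, k)
    data.frame(label = labs, angle_deg = runif(k, 13, 20),
               stringsAsFactors = FALSE)
  })
  anyRibs <- nrow(config@ribPlan) && any(config@ribPlan$present)
  slots <- paste0(config@ribPlan$side, config@ribPlan$index)
  removable <- setdiff(slots, "left5")
  affected <- ((seq_len(n) - 1L) %% config@absentDen) < config@absentNum
  absentSlots <- lapply(seq_len(n), function(i) {
    if (!anyRibs || !affected[i]) return(character(0))
    sample(removable, min(config@absentPerSpecimen, length(removable)))
  })

  lc5 <- config@ribPlan$targetLc[config@ribPlan$side == "left" &
                                   config@ribPlan$index == 5L]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg@targetHeightMm <- max(0.5, config@targetHeightMm + config@heightSd * zH[i])
    cfg@wedgePlan <- wedgePlans[[i]]
    if (anyRibs && !is.na(lc5) && config@ribLcSd > 0) {
      mult <- max(0.2, (lc5 + config@ribLcSd * zL[i]) / lc5)
      cfg@ribPlan$targetLc <- config@ribPlan$targetLc * mult
    }
    if (length(absentSlots[[i]])) {
      drop <- slots %in% absentSlots[[i]]
      cfg@ribPlan$present[drop] <- FALSE
    }
    sid <- sprintf("%s_E%d_%02d", config@group, config@stage, i)
    spineSeed <- baseSeed + i - 1L
    sp <- generateSpine(cfg, seed = spineSeed, id = sid)
    rb <- generateRibs(cfg, sp, seed = spineSeed + 1000003L)
    out[[i]] <- Specimen(sp, rb)
  }
  out
}
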