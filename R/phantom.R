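# Synthetic abdominal CT phantoms with ground-truth masks. The phantoms
# reproduce the intensity regime the method assumes at portal-venous phase:
# a bright, smoothly perturbed quasi-ellipsoidal liver, darker spherical
# tumors strictly inside it, a soft-tissue body on an air background with
# bone structures (spine, rib arcs), and additive Gaussian noise. All
# intensities are design conventions inside the -50..250 HU working window,
# not measurements of real tissue.

#' Generate one synthetic CT phantom with ground truth
#'
#' Deterministic given `spec@seed`. The liver is an ellipsoid whose radius
#' is modulated by a low-frequency angular perturbation (so the level set
#' faces non-trivial curvature); tumors are placed where the distance to the
#' liver boundary (in-plane pixel metric, slice axis weighted by the spacing
#' ratio) exceeds the tumor radius plus a 2 px margin, guaranteeing
#' tumor-inside-liver with margin. The liver mask includes tumor voxels
#' (tumors lie inside the liver envelope).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `volume` ([CTVolume-class]), `liver` and `tumor`
#'   ([BinaryMask-class]), and `params` (every drawn parameter).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  set.seed(spec@seed)
  d <- spec@dim
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  hz <- spec@spacing[3] / spec@spacing[1]
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  # body: soft-tissue ellipse on air
  cbi <- (nr + 1) / 2
  cbj <- (nc + 1) / 2
  abi <- 0.42 * nr
  abj <- 0.46 * nc
  rho2d <- sqrt(((ii - cbi) / abi)^2 + ((jj - cbj) / abj)^2)
  body2d <- rho2d <= 1
  vol <- array(spec@airHU, dim = d)
  nbody <- sum(body2d)
  for (k in seq_len(nz))
    vol[, , k][body2d] <- rnorm(nbody, spec@softHU, 8)

  # bone: posterior spine cylinder and rib arcs near the body boundary
  spine <- ((ii - (cbi + 0.30 * nr))^2 + (jj - cbj)^2) <= (0.055 * nr)^2
  theta2d <- atan2(ii - cbi, jj - cbj)
  ribs <- body2d & rho2d >= 0.92 & rho2d <= 0.985 &
    abs(sin(4 * theta2d)) > 0.75
  for (k in seq_len(nz)) {
    sl <- vol[, , k]
    sl[spine] <- spec@boneHU
    if (k %% 3L != 0L) sl[ribs] <- spec@boneHU
    vol[, , k] <- sl
  }

  # liver: perturbed ellipsoid, drawn placement unless given
  lc <- spec@liverCenter
  la <- spec@liverAxes
  if (any(is.na(lc)))
    lc <- c(runif(1, 0.36, 0.44) * nr, runif(1, 0.34, 0.44) * nc,
            runif(1, 0.45, 0.55) * nz)
  if (any(is.na(la)))
    la <- c(runif(1, 0.18, 0.25) * nr, runif(1, 0.22, 0.30) * nc,
            runif(1, 0.24, 0.36) * nz)
  ph1 <- runif(1, 0, 2 * pi)
  ph2 <- runif(1, 0, 2 * pi)
  liver <- array(FALSE, dim = d)
  for (k in seq_len(nz)) {
    dz <- (k - lc[3]) / la[3]
    if (abs(dz) > 1 + spec@perturbAmp) next
    dy <- (ii - lc[1]) / la[1]
    dx <- (jj - lc[2]) / la[2]
    rho <- sqrt(dx^2 + dy^2 + dz^2)
    th <- atan2(dy, dx)
    pert <- spec@perturbAmp * (0.6 * sin(3 * th + ph1) +
                                 0.4 * sin(2 * th + ph2))
    liver[, , k] <- (rho <= 1 + pert) & body2d & !spine
  }
  nliv <- sum(liver)
  if (nliv == 0L)
    stopWithClass("liver specification produced an empty region",
                  "hepasegSpecError")
  vol[liver] <- rnorm(nliv, spec@liverHU, spec@liverSD)

  # tumors: centers sampled where the in-liver distance allows radius + 2 px
  edt <- cpp_edt(array(as.integer(!liver), dim = d), c(1, 1, hz))
  count <- spec@tumorCount
  if (is.na(count)) count <- sample(0:4, 1)
  tumor <- array(FALSE, dim = d)
  maxFeasible <- max(edt[liver]) - 2
  if (count > 0 && maxFeasible < spec@tumorRadius[1])
    stopWithClass("tumor radius range does not fit inside the liver",
                  "hepasegSpecError")
  radii <- numeric(0)
  for (t in seq_len(count)) {
    r <- min(runif(1, spec@tumorRadius[1], spec@tumorRadius[2]), maxFeasible)
    cand <- which(liver & edt >= r + 2)
    ctr <- arrayInd(cand[sample.int(length(cand), 1)], d)
    rz <- r / hz
    k0 <- max(1, floor(ctr[3] - rz)):min(nz, ceiling(ctr[3] + rz))
    for (k in k0) {
      dz2 <- ((k - ctr[3]) * hz)^2
      if (dz2 > r^2) next
      rr <- sqrt(r^2 - dz2)
      sel <- (ii - ctr[1])^2 + (jj - ctr[2])^2 <= rr^2
      if (!any(sel)) next
      sl <- vol[, , k]
      sl[sel] <- rnorm(sum(sel), spec@tumorHU, spec@tumorSD)
      vol[, , k] <- sl
      tm <- tumor[, , k]
      tm[sel] <- TRUE
      tumor[, , k] <- tm
    }
    radii <- c(radii, r)
  }

  vol <- vol + array(rnorm(prod(d), 0, spec@noiseSD), dim = d)
  list(volume = ctVolume(vol, spacing = spec@spacing),
       liver = binaryMask(liver, spacing = spec@spacing),
       tumor = binaryMask(tumor, spacing = spec@spacing),
       params = list(seed = spec@seed, liverCenter = lc, liverAxes = la,
                     tumorCount = count, tumorRadii = radii))
}

#' Generate a corpus of phantoms
#'
#' Per-case parameters (liver placement and size, tumor count and radii) are
#' drawn inside [generatePhantom()] from per-case seeds derived from `seed`;
#' the manifest records every drawn parameter, and regenerating from the
#' manifest's seeds reproduces the corpus exactly.
#'
#' @param n number of cases (>= 1).
#' @param spec base [PhantomSpec-class]; its seed is ignored.
#' @param seed corpus-level seed.
#' @param outDir optional directory; when given, writes
#'   `case_XXXX/volume.nii.gz`, `liver.nii.gz`, `tumor.nii.gz` and
#'   `manifest.csv`.
#' @return list with `cases` (list of phantom triples, named case_XXXX) and
#'   `manifest` (data.frame).
#' @export
generateCorpus <- function(n, spec = phantomSpec(), seed = 1L,
                           outDir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  caseSeeds <- sample.int(.Machine$integer.max, n)
  cases <- vector("list", n)
  rows <- vector("list", n)
  ids <- sprintf("case_%04d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- spec
    sp@seed <- caseSeeds[i]
    sp@tumorCount <- NA_integer_
    ph <- generatePhantom(sp)
    cases[[i]] <- ph
    rows[[i]] <- data.frame(
      case_id = ids[i], seed = caseSeeds[i],
      liver_ci = ph$params$liverCenter[1],
      liver_cj = ph$params$liverCenter[2],
      liver_ck = ph$params$liverCenter[3],
      liver_ai = ph$params$liverAxes[1],
      liver_aj = ph$params$liverAxes[2],
      liver_ak = ph$params$liverAxes[3],
      tumor_count = ph$params$tumorCount,
      tumor_radii = paste(round(ph$params$tumorRadii, 2), collapse = ";"))
    if (!is.null(outDir)) {
      dd <- file.path(outDir, ids[i])
      dir.create(dd, recursive = TRUE, showWarnings = FALSE)
      writeVolume(ph$volume, file.path(dd, "volume.nii.gz"))
      writeMask(ph$liver, ph$volume, file.path(dd, "liver.nii.gz"))
      writeMask(ph$tumor, ph$volume, file.path(dd, "tumor.nii.gz"))
    }
  }
  names(cases) <- ids
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    write.csv(manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
  list(cases = cases, manifest = manifest)
}
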