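# Synthetic 4-channel fluorescence image simulator.
#
# Emulates the layout of per-channel confocal captures: green = protein of
# interest, blue = DAPI nucleus, red = microtubules, yellow = endoplasmic
# reticulum.  Each of the 13 localization classes has a qualitative pattern
# renderer (filled nucleus, boundary rings, radial filaments, scattered
# vesicles, ...) painted inside parametric cell/nucleus ellipses, so every
# generated sample carries exact ground-truth masks.

# ---- geometry ------------------------------------------------------------

.grid_rows <- function(side) matrix(seq_len(side), side, side)
.grid_cols <- function(side) matrix(seq_len(side), side, side, byrow = TRUE)

ellipse_mask <- function(side, center, axes, theta) {
  dy <- .grid_rows(side) - center[1]
  dx <- .grid_cols(side) - center[2]
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

.stamp_disc <- function(mask, r, c, radius) {
  side <- nrow(mask)
  r0 <- max(1, floor(r - radius)); r1 <- min(side, ceiling(r + radius))
  c0 <- max(1, floor(c - radius)); c1 <- min(side, ceiling(c + radius))
  if (r0 > r1 || c0 > c1) return(mask)
  for (i in r0:r1) for (j in c0:c1)
    if ((i - r)^2 + (j - c)^2 <= radius^2) mask[i, j] <- TRUE
  mask
}

.draw_curve <- function(mask, pts, width = 1) {
  # pts: n x 2 matrix of (row, col); rasterize by stamping small discs
  rad <- max(0.6, width / 2)
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    for (t in seq(0, 1, length.out = max(2L, ceiling(len * 2)))) {
      q <- p0 + t * (p1 - p0)
      mask <- .stamp_disc(mask, q[1], q[2], rad)
    }
  }
  mask
}

# Morphology parameters per "cell line" tag: relative cell radius and the
# minor/major axis ratio range.  lineB cells are large and elongated, lineC
# small and round; lineC plays the minority cell-line role downstream.
.morphologies <- list(
  lineA = list(rel_radius = c(0.14, 0.18), axis_ratio = c(0.75, 0.95)),
  lineB = list(rel_radius = c(0.20, 0.26), axis_ratio = c(0.45, 0.65)),
  lineC = list(rel_radius = c(0.09, 0.12), axis_ratio = c(0.85, 1.00))
)

#' Morphology tags known to the simulator
#' @return Character vector of cell-line-like tags.
#' @export
morphology_tags <- function() names(.morphologies)

#' Place random non-overlapping cell geometries on an image canvas
#'
#' Each geometry is a parametric cell ellipse with a strictly interior
#' nucleus ellipse and a centrosome point in the cytoplasm.  The morphology
#' tag selects size/eccentricity distributions, standing in for cell-line
#' heterogeneity.
#'
#' @param morphology_tag One of [morphology_tags()].
#' @param image_side Canvas side in pixels (>= 64).
#' @param n_cells Number of cells to attempt (1-6); random if `NULL`.
#' @param seed Optional integer seed for reproducible geometry.
#' @return List of geometries; each has `cell`, `nucleus` (logical masks),
#'   parametric fields (`cell_center`, `cell_axes`, `theta`, `nuc_center`,
#'   `nuc_axes`) and `centrosome` (row, col).
#' @export
render_geometry <- function(morphology_tag, image_side, n_cells = NULL,
                            seed = NULL) {
  if (image_side < 64) stop("image_side must be at least 64")
  morph <- .morphologies[[morphology_tag]]
  if (is.null(morph)) stop("unknown morphology tag: ", morphology_tag)
  with_seed(seed, {
    if (is.null(n_cells)) n_cells <- sample(1:6, 1)
    occupied <- matrix(FALSE, image_side, image_side)
    geoms <- list()
    for (i in seq_len(n_cells)) {
      for (try in 1:40) {
        a <- runif(1, morph$rel_radius[1], morph$rel_radius[2]) * image_side
        b <- a * runif(1, morph$axis_ratio[1], morph$axis_ratio[2])
        theta <- runif(1, 0, pi)
        center <- runif(2, a + 2, image_side - a - 1)
        cell <- ellipse_mask(image_side, center, c(a, b), theta)
        if (any(cell & occupied)) next
        nuc_axes <- c(a, b) * 0.45
        nuc_center <- center + runif(2, -0.08, 0.08) * c(a, b)
        nucleus <- ellipse_mask(image_side, nuc_center, nuc_axes, theta)
        # centrosome: just outside the nucleus, inside the cell
        centro <- NULL
        for (k in 1:20) {
          phi <- runif(1, 0, 2 * pi)
          d <- 1.4 * mean(nuc_axes)
          pt <- nuc_center + d * c(cos(phi), sin(phi))
          ri <- round(pt[1]); ci <- round(pt[2])
          if (ri >= 1 && ci >= 1 && ri <= image_side && ci <= image_side &&
              cell[ri, ci] && !nucleus[ri, ci]) { centro <- c(ri, ci); break }
        }
        if (is.null(centro)) next
        occupied <- occupied | cell
        geoms[[length(geoms) + 1]] <- list(
          cell = cell, nucleus = nucleus, centrosome = centro,
          cell_center = center, cell_axes = c(a, b), theta = theta,
          nuc_center = nuc_center, nuc_axes = nuc_axes,
          morphology_tag = morphology_tag)
        break
      }
    }
    if (!length(geoms)) stop("could not place any cell on a ",
                             image_side, "px canvas")
    geoms
  })
}

# ---- per-class pattern renderers -----------------------------------------

.render_class_cell <- function(code, g) {
  side <- nrow(g$cell)
  cyto <- g$cell & !g$nucleus
  blank <- matrix(FALSE, side, side)
  scale_r <- side / 64  # renderer sizes are tuned at a 64 px canvas
  switch(code,
    NU = g$nucleus,
    NI = {
      m <- blank
      for (i in seq_len(sample(1:4, 1))) {
        phi <- runif(1, 0, 2 * pi); rr <- runif(1, 0, 0.55)
        ctr <- g$nuc_center + rr * g$nuc_axes * c(cos(phi), sin(phi))
        m <- .stamp_disc(m, ctr[1], ctr[2], max(1.2, 0.22 * mean(g$nuc_axes)))
      }
      m & g$nucleus
    },
    NM = ellipse_mask(side, g$nuc_center, g$nuc_axes * 1.08, g$theta) &
         !ellipse_mask(side, g$nuc_center, g$nuc_axes * 0.78, g$theta) & g$cell,
    CY = cyto,
    PM = g$cell & !ellipse_mask(side, g$cell_center, g$cell_axes * 0.90, g$theta),
    VE = {
      m <- blank
      idx <- which(cyto)
      n_dots <- min(length(idx), sample(8:20, 1))
      for (p in idx[sample.int(length(idx), n_dots)]) {
        ri <- (p - 1) %% side + 1; ci <- (p - 1) %/% side + 1
        m <- .stamp_disc(m, ri, ci, max(1, 0.9 * scale_r))
      }
      m & cyto
    },
    MC = {
      m <- blank
      idx <- which(cyto)
      for (i in seq_len(sample(4:8, 1))) {
        p <- idx[sample.int(length(idx), 1)]
        r0 <- (p - 1) %% side + 1; c0 <- (p - 1) %/% side + 1
        phi <- runif(1, 0, 2 * pi); len <- runif(1, 3, 6) * scale_r
        bend <- runif(1, -0.8, 0.8)
        ts <- seq(0, 1, length.out = 6)
        pts <- cbind(r0 + ts * len * cos(phi + bend * ts),
                     c0 + ts * len * sin(phi + bend * ts))
        m <- .draw_curve(m, pts, width = 1.1)
      }
      m & cyto
    },
    MT = {
      m <- blank
      for (phi in seq(0, 2 * pi, length.out = sample(9:14, 1))) {
        reach <- 1.1 * max(g$cell_axes)
        pts <- rbind(g$centrosome,
                     g$centrosome + reach * c(cos(phi), sin(phi)))
        m <- .draw_curve(m, pts, width = 1)
      }
      m <- m & g$cell
      m | .stamp_disc(blank, g$centrosome[1], g$centrosome[2], 1.2)
    },
    CE = .stamp_disc(blank, g$centrosome[1], g$centrosome[2],
                     max(1.5, 1.2 * scale_r)),
    GA = {
      phi <- runif(1, 0, 2 * pi)
      ctr <- g$nuc_center + 1.35 * g$nuc_axes * c(cos(phi), sin(phi))
      m <- .stamp_disc(blank, ctr[1], ctr[2], max(2, 0.45 * mean(g$nuc_axes)))
      out <- m & cyto
      if (!any(out)) .stamp_disc(blank, g$centrosome[1], g$centrosome[2],
                                 max(2, 0.45 * mean(g$nuc_axes))) & cyto
      else out
    },
    ER = {
      band <- ellipse_mask(side, g$nuc_center, g$nuc_axes * 1.9, g$theta) &
              !g$nucleus & g$cell
      speck <- matrix(runif(side * side) < 0.55, side, side)
      band & speck
    },
    AF = {
      m <- blank
      for (i in seq_len(sample(2:4, 1))) {
        phi <- runif(1, 0, pi)
        off <- runif(1, -0.5, 0.5) * min(g$cell_axes)
        dirv <- c(cos(phi), sin(phi)); nrm <- c(-sin(phi), cos(phi))
        p0 <- g$cell_center + off * nrm - 1.2 * max(g$cell_axes) * dirv
        p1 <- g$cell_center + off * nrm + 1.2 * max(g$cell_axes) * dirv
        m <- .draw_curve(m, rbind(p0, p1), width = 1.1)
      }
      m & g$cell
    },
    IF = {
      m <- blank
      idx <- which(cyto)
      for (i in seq_len(sample(3:5, 1))) {
        p <- idx[sample.int(length(idx), 1)]
        r0 <- (p - 1) %% side + 1; c0 <- (p - 1) %/% side + 1
        phi <- runif(1, 0, 2 * pi)
        len <- runif(1, 8, 14) * scale_r
        amp <- runif(1, 1, 2.5) * scale_r
        ts <- seq(0, 1, length.out = 12)
        pts <- cbind(
          r0 + ts * len * cos(phi) + amp * sin(4 * pi * ts) * -sin(phi),
          c0 + ts * len * sin(phi) + amp * sin(4 * pi * ts) * cos(phi))
        m <- .draw_curve(m, pts, width = 1)
      }
      m & cyto
    },
    stop("no renderer for class ", code)
  )
}

# ---- label sampling ------------------------------------------------------

#' Default multilocalization co-occurrence whitelist
#'
#' Pairs of classes allowed to appear together in one synthetic sample, so
#' multi-label draws stay spatially coherent (a nucleolar signal co-occurs
#' with a nuclear one, vesicles with cytosol, and so on).
#'
#' @return 13 x 13 symmetric logical matrix; `TRUE` marks an allowed pair.
#' @export
default_cooccurrence <- function() {
  cls <- organelle_classes()
  m <- matrix(FALSE, 13, 13, dimnames = list(cls, cls))
  pairs <- rbind(
    c("NU", "NI"), c("NU", "NM"), c("NU", "CY"), c("NU", "VE"), c("NU", "MT"),
    c("NU", "GA"), c("NU", "ER"), c("NU", "MC"), c("NU", "PM"), c("NU", "CE"),
    c("CY", "VE"), c("CY", "MT"), c("CY", "MC"), c("CY", "PM"), c("CY", "AF"),
    c("CY", "GA"), c("CY", "ER"), c("CY", "IF"), c("CY", "CE"),
    c("NI", "NM"), c("VE", "GA"), c("VE", "MC"), c("MT", "CE"),
    c("AF", "PM"), c("ER", "GA"), c("MC", "ER"))
  for (i in seq_len(nrow(pairs))) {
    m[pairs[i, 1], pairs[i, 2]] <- TRUE
    m[pairs[i, 2], pairs[i, 1]] <- TRUE
  }
  m
}

#' Default marginal class weights for the simulator
#'
#' Hand-set sampling weights echoing the strong class imbalance typical of
#' large localization datasets: nucleus and cytosol dominate, actin
#' filaments / ER / intermediate filaments are rare.
#'
#' @return Named numeric 13-vector summing to 1.
#' @export
default_class_weights <- function() {
  w <- c(AF = 0.02, CE = 0.03, CY = 0.22, ER = 0.02, GA = 0.05, IF = 0.01,
         MT = 0.07, MC = 0.07, NM = 0.04, NI = 0.08, NU = 0.25, PM = 0.04,
         VE = 0.10)
  w[organelle_classes()]
}

#' Draw a multi-label class set
#'
#' The number of simultaneous localizations k in 1..4 is drawn from
#' `multiloc_probs` (default: the observed multilocalization strata of large
#' protein-atlas style data, 60.6 / 33.3 / 5.8 / 0.3 percent), then classes
#' are accumulated subject to the pairwise co-occurrence whitelist.
#'
#' @param multiloc_probs Probabilities for 1-4 simultaneous classes
#'   (must sum to 1).
#' @param cooccurrence 13 x 13 logical whitelist, see [default_cooccurrence()].
#' @param class_weights Marginal sampling weights over the 13 classes.
#' @param allowed_classes Restrict draws to these codes (default all 13).
#' @param seed Optional seed.
#' @return Binary label 13-vector (named, canonical order).
#' @export
sample_label_set <- function(multiloc_probs = c(0.606, 0.333, 0.058, 0.003),
                             cooccurrence = default_cooccurrence(),
                             class_weights = default_class_weights(),
                             allowed_classes = organelle_classes(),
                             seed = NULL) {
  if (abs(sum(multiloc_probs) - 1) > 1e-9)
    stop("multiloc_probs must sum to 1")
  if (!length(allowed_classes))
    stop("allowed_classes is empty: unsatisfiable configuration")
  allowed_classes <- match.arg(allowed_classes, organelle_classes(),
                               several.ok = TRUE)
  w <- class_weights[allowed_classes]
  with_seed(seed, {
    k <- sample.int(4, 1, prob = multiloc_probs)
    for (attempt in 1:200) {
      chosen <- sample(allowed_classes, 1, prob = w)
      while (length(chosen) < k) {
        cand <- setdiff(allowed_classes, chosen)
        ok <- vapply(cand, function(c0) all(cooccurrence[c0, chosen]), TRUE)
        cand <- cand[ok]
        if (!length(cand)) break
        chosen <- c(chosen, sample(cand, 1,
                                   prob = class_weights[cand]))
      }
      if (length(chosen) == k) return(label_vector(chosen))
    }
    stop("co-occurrence whitelist cannot produce a set of size ", k,
         " from the allowed classes")
  })
}

# ---- sample rendering ----------------------------------------------------

#' Render one synthetic 4-channel sample
#'
#' The green channel is the union of class-specific patterns over all
#' present classes, with per-cell intensity jitter and additive Gaussian
#' background noise; blue carries the filled nuclei, red a radial
#' microtubule-like reference and yellow a perinuclear reticular reference.
#'
#' @param geometry List of cell geometries from [render_geometry()].
#' @param labels Binary 13-vector with at least one present class.
#' @param noise_level Standard deviation of additive background noise
#'   (0 disables it).
#' @param jitter Relative per-cell intensity jitter (0.2 = +/-20%).
#' @param seed Optional seed.
#' @return A `protloc_sample`: list with `image` (side x side x 4 array in
#'   `[0,1]`, channels green/blue/red/yellow), `labels`, `truth_masks`
#'   (named list of logical masks for present classes), `cell_line`.
#' @export
render_sample <- function(geometry, labels, noise_level = 0.02,
                          jitter = 0.2, seed = NULL) {
  stopifnot(length(labels) == n_classes())
  present <- label_codes(labels)
  if (!length(present)) stop("labels must contain at least one present class")
  side <- nrow(geometry[[1]]$cell)
  with_seed(seed, {
    base_int <- 0.8
    jit <- function() base_int * runif(1, 1 - jitter, 1 + jitter)
    green <- matrix(0, side, side)
    truth <- list()
    for (code in present) {
      cm <- matrix(FALSE, side, side)
      for (g in geometry) {
        m <- .render_class_cell(code, g)
        green <- pmax(green, m * jit())
        cm <- cm | m
      }
      truth[[code]] <- cm
    }
    blue <- matrix(0, side, side)
    red <- matrix(0, side, side)
    yellow <- matrix(0, side, side)
    for (g in geometry) {
      blue <- pmax(blue, g$nucleus * jit())
      red <- pmax(red, .render_class_cell("MT", g) * (0.85 * jit()))
      yellow <- pmax(yellow, .render_class_cell("ER", g) * (0.85 * jit()))
    }
    img <- array(0, dim = c(side, side, 4))
    img[, , 1] <- green; img[, , 2] <- blue
    img[, , 3] <- red; img[, , 4] <- yellow
    if (noise_level > 0)
      img <- img + array(rnorm(length(img), 0, noise_level), dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    structure(list(image = img, labels = labels, truth_masks = truth,
                   cell_line = geometry[[1]]$morphology_tag),
              class = "protloc_sample")
  })
}

# ---- dataset generation --------------------------------------------------

#' Simulator configuration
#'
#' @param image_side Canvas side in pixels (64 for tests, 256 for demo runs).
#' @param multiloc_probs Probabilities of 1-4 simultaneous classes.
#' @param class_weights Marginal class weights.
#' @param cooccurrence Pairwise whitelist matrix.
#' @param allowed_classes Classes the simulator may draw.
#' @param noise_level,jitter Noise model, see [render_sample()].
#' @param morphology_freqs Named frequencies of the cell-line tags; the
#'   default keeps lineC a 10% minority line.
#' @param n_cells Cells per image (`NULL` = random 1-6).
#' @return List of class `protloc_sim_config`.
#' @export
sim_config <- function(image_side = 64,
                       multiloc_probs = c(0.606, 0.333, 0.058, 0.003),
                       class_weights = default_class_weights(),
                       cooccurrence = default_cooccurrence(),
                       allowed_classes = organelle_classes(),
                       noise_level = 0.02, jitter = 0.2,
                       morphology_freqs = c(lineA = 0.45, lineB = 0.45,
                                            lineC = 0.10),
                       n_cells = NULL) {
  structure(as.list(environment()), class = "protloc_sim_config")
}

#' Generate an in-memory synthetic dataset
#'
#' @param n Number of samples (>= 1).
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return List with `images` (side x side x 4 x n array), `labels`
#'   (n x 13 binary matrix), `cell_line` (n), `sample_id` (n) and `samples`
#'   (list of `protloc_sample`, carrying the truth masks).
#' @export
simulate_dataset <- function(n, config = sim_config(), seed = 1) {
  if (n < 1) stop("n must be at least 1")
  with_seed(seed, {
    side <- config$image_side
    images <- array(0, dim = c(side, side, 4, n))
    labels <- matrix(0L, n, n_classes(),
                     dimnames = list(NULL, organelle_classes()))
    cell_line <- character(n)
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      tag <- sample(names(config$morphology_freqs), 1,
                    prob = config$morphology_freqs)
      geom <- render_geometry(tag, side, n_cells = config$n_cells)
      lab <- sample_label_set(config$multiloc_probs, config$cooccurrence,
                              config$class_weights, config$allowed_classes)
      s <- render_sample(geom, lab, config$noise_level, config$jitter)
      images[, , , i] <- s$image
      labels[i, ] <- lab
      cell_line[i] <- tag
      samples[[i]] <- s
    }
    list(images = images, labels = labels, cell_line = cell_line,
         sample_id = sprintf("s%05d", seq_len(n)), samples = samples)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes the per-channel grayscale PNG layout
#' (`<id>_green.png`, `<id>_blue.png`, `<id>_red.png`, `<id>_yellow.png`)
#' plus `labels.csv` with columns `sample_id, cell_line, classes` (classes
#' space-separated), and optionally one multi-page ground-truth mask TIFF
#' per sample (pages in canonical class order, absent classes all-zero).
#'
#' @param n Number of samples.
#' @param out_dir Output directory (created if missing).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param write_masks Also write `<id>_masks.tiff` ground-truth stacks.
#' @return Invisibly, the label table data frame.
#' @export
generate_dataset <- function(n, out_dir, config = sim_config(), seed = 1,
                             write_masks = FALSE) {
  if (n < 1) stop("n must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ds <- simulate_dataset(n, config, seed)
  chans <- c("green", "blue", "red", "yellow")
  for (i in seq_len(n)) {
    id <- ds$sample_id[i]
    for (ch in seq_along(chans))
      png::writePNG(ds$images[, , ch, i],
                    file.path(out_dir, paste0(id, "_", chans[ch], ".png")))
    if (write_masks) {
      stack <- lapply(organelle_classes(), function(code) {
        m <- ds$samples[[i]]$truth_masks[[code]]
        if (is.null(m)) matrix(0, config$image_side, config$image_side)
        else m * 1
      })
      tiff::writeTIFF(stack, file.path(out_dir, paste0(id, "_masks.tiff")))
    }
  }
  tab <- data.frame(
    sample_id = ds$sample_id,
    cell_line = ds$cell_line,
    classes = apply(ds$labels, 1, function(r)
      paste(organelle_classes()[r > 0], collapse = " ")),
    stringsAsFactors = FALSE)
  write.csv(tab, file.path(out_dir, "labels.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(tab)
}

#' Read a per-channel PNG/TIFF dataset from disk
#'
#' Counterpart of [generate_dataset()]; also the entry point for real data
#' following the same per-channel layout.
#'
#' @param dir Directory holding `labels.csv` and the channel files.
#' @return List with `images`, `labels`, `cell_line`, `sample_id` as in
#'   [simulate_dataset()] (without truth masks).
#' @export
read_dataset <- function(dir) {
  tab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  chans <- c("green", "blue", "red", "yellow")
  read1 <- function(path) {
    if (file.exists(path)) return(png::readPNG(path))
    alt <- sub("\\.png$", ".tiff", path)
    if (file.exists(alt)) return(tiff::readTIFF(alt))
    stop("missing channel file: ", path)
  }
  first <- read1(file.path(dir, paste0(tab$sample_id[1], "_green.png")))
  side <- nrow(first)
  n <- nrow(tab)
  images <- array(0, dim = c(side, ncol(first), 4, n))
  for (i in seq_len(n))
    for (ch in seq_along(chans))
      images[, , ch, i] <- read1(file.path(
        dir, paste0(tab$sample_id[i], "_", chans[ch], ".png")))
  labels <- t(vapply(tab$classes, label_vector, integer(n_classes())))
  dimnames(labels) <- list(NULL, organelle_classes())
  list(images = images, labels = labels, cell_line = tab$cell_line,
       sample_id = tab$sample_id)
}
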