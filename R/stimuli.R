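# Procedural stimulus generation: verniers, shape groups, cuboids, and the
# (un)crowding test compositions, with the training-time noise/contrast
# augmentation. Images are matrices with rows = y (1 = top), cols = x,
# intensities in [0, 1]. Drawing is additive with clipping at 1; no
# anti-aliasing, so pixel counts are exact and testable.

#' Stimulus geometry configuration
#'
#' Canvas and shape dimensions in pixels for one experiment. All geometry the
#' renderers use is collected here so that every dimension can be varied.
#' Widths default to odd values so that a stimulus centred on the canvas is
#' exactly mirror-symmetric about the central column.
#'
#' @param experiment 1 (shape groups: squares, circles, ...) or 2 (lines,
#'   cuboids, scrambled cuboids).
#' @param height,width Canvas size in pixels.
#' @param shape_size Side/diameter of one experiment-1 flanker shape (odd).
#' @param vernier_length Length of each vernier bar in pixels.
#' @param vernier_gap Vertical gap between the two bars in pixels (odd keeps
#'   the vernier vertically symmetric about its centre).
#' @param vernier_offset_px Default horizontal offset magnitude at test time.
#' @param train_offsets Set of offset magnitudes sampled during training.
#' @param spacing Horizontal gap between adjacent flanker shapes in a group.
#' @param jitter Maximum absolute (x, y) jitter of the stimulus centre in
#'   training frames ("roughly centered").
#' @param shapes Character vector of the six experiment-1 flanker classes.
#' @param line_length Length of an experiment-2 line (= cuboid front height).
#' @param line_spacing_range Integer range for random gaps between grouped
#'   lines (experiment 2 training).
#' @param line_group_sizes Group sizes for experiment-2 line stimuli.
#' @param cuboid_width Width of a cuboid front face in pixels.
#' @param cuboid_depth Length of the 45-degree oblique edges in pixels.
#' @param pair_spacing_range Allowed gap (pixels) between the two facing
#'   cuboids of a pair; the paper's range is 1-6.
#' @param flank_dist Test-time distance from the vernier centre to each
#'   experiment-2 flanker's innermost edge.
#' @param fg Foreground intensity of drawn pixels before augmentation.
#' @return An object of class `stim_config` (a list).
#' @export
stim_config <- function(experiment = 1,
                        height = 31,
                        width = 73,
                        shape_size = 11,
                        vernier_length = 2,
                        vernier_gap = 1,
                        vernier_offset_px = 2,
                        train_offsets = c(2, 4),
                        spacing = 4,
                        jitter = c(4, 2),
                        shapes = c("square", "circle", "hexagon",
                                   "octagon", "diamond", "star"),
                        line_length = 11,
                        line_spacing_range = c(1, 6),
                        line_group_sizes = c(2, 4, 6),
                        cuboid_width = 7,
                        cuboid_depth = 4,
                        pair_spacing_range = c(1, 6),
                        flank_dist = 6,
                        fg = 1.0) {
  stopifnot(experiment %in% c(1, 2), height >= 5, width >= 5,
            shape_size %% 2 == 1, vernier_gap %% 2 == 1,
            vernier_length >= 1, vernier_offset_px >= 1,
            spacing >= 1, fg > 0, fg <= 1,
            length(shapes) >= 1,
            pair_spacing_range[1] >= 1, pair_spacing_range[2] <= 6)
  structure(list(experiment = experiment, height = height, width = width,
                 shape_size = shape_size, vernier_length = vernier_length,
                 vernier_gap = vernier_gap,
                 vernier_offset_px = vernier_offset_px,
                 train_offsets = train_offsets, spacing = spacing,
                 jitter = jitter, shapes = shapes,
                 line_length = line_length,
                 line_spacing_range = line_spacing_range,
                 line_group_sizes = line_group_sizes,
                 cuboid_width = cuboid_width, cuboid_depth = cuboid_depth,
                 pair_spacing_range = pair_spacing_range,
                 flank_dist = flank_dist, fg = fg),
            class = "stim_config")
}

#' Small stimulus preset used by the scaled-down test/acceptance pipeline
#'
#' A 17 x 49 canvas with 7-pixel shapes; the same geometry rules as
#' [stim_config()] but sized so that networks train in seconds on one CPU.
#' @inheritParams stim_config
#' @return A `stim_config`.
#' @export
stim_config_small <- function(experiment = 1) {
  stim_config(experiment = experiment, height = 25, width = 71,
              shape_size = 11, vernier_length = 3, vernier_gap = 1,
              vernier_offset_px = 2, train_offsets = c(2, 4), spacing = 3,
              jitter = c(2, 1), line_length = 9, cuboid_width = 7,
              cuboid_depth = 3, flank_dist = 5)
}

#' Construct a stimulus frame
#'
#' @param image Matrix of intensities in `[0, 1]`.
#' @param shape_class Class label (e.g. "vernier", "square", "lines").
#' @param n_repetitions Number of repeated shapes in the frame.
#' @param vernier_offset "left", "right" or "none".
#' @param x,y Pixel coordinates of the stimulus centroid.
#' @param condition Optional test-condition name.
#' @return An object of class `stimulus_frame`.
#' @export
stimulus_frame <- function(image, shape_class, n_repetitions = 1L,
                           vernier_offset = "none", x, y, condition = NA_character_) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 1),
            vernier_offset %in% c("left", "right", "none"))
  structure(list(image = image, shape_class = shape_class,
                 n_repetitions = as.integer(n_repetitions),
                 vernier_offset = vernier_offset,
                 x = as.integer(x), y = as.integer(y),
                 condition = condition),
            class = "stimulus_frame")
}

#' @export
print.stimulus_frame <- function(x, ...) {
  cat(sprintf("<stimulus_frame %dx%d: %s x%d, vernier=%s at (%d,%d)%s>\n",
              nrow(x$image), ncol(x$image), x$shape_class, x$n_repetitions,
              x$vernier_offset, x$x, x$y,
              if (is.na(x$condition)) "" else paste0(", cond=", x$condition)))
  invisible(x)
}

# ---- low-level drawing -----------------------------------------------------

# Bresenham line, inclusive endpoints; returns a 2-col (x, y) integer matrix.
.bres <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 <  dx) { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

# closed polygon outline through integer vertices; vertices is 2-col (x, y)
.polygon_pts <- function(vertices) {
  k <- nrow(vertices)
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    seg <- .bres(vertices[i, 1], vertices[i, 2], vertices[j, 1], vertices[j, 2])
    seg[-nrow(seg), , drop = FALSE] # half-open: endpoint belongs to next edge
  }))
  unique(pts)
}

# pixel offsets (relative to shape centre) of one experiment-1 shape outline
.shape_pts <- function(shape, size) {
  r <- (size - 1L) / 2L
  switch(shape,
    square = {
      s <- seq(-r, r)
      unique(rbind(cbind(s, -r), cbind(s, r), cbind(-r, s), cbind(r, s)))
    },
    circle = {
      # midpoint circle
      x <- r; y <- 0L; err <- 1L - r
      pts <- NULL
      while (x >= y) {
        pts <- rbind(pts,
                     c(x, y), c(y, x), c(-y, x), c(-x, y),
                     c(-x, -y), c(-y, -x), c(y, -x), c(x, -y))
        y <- y + 1L
        if (err < 0) err <- err + 2L * y + 1L
        else { x <- x - 1L; err <- err + 2L * (y - x) + 1L }
      }
      unique(pts)
    },
    diamond = .polygon_pts(rbind(c(0, -r), c(r, 0), c(0, r), c(-r, 0))),
    hexagon = {
      ang <- (0:5) * pi / 3
      .polygon_pts(unique(cbind(round(r * cos(ang)), round(r * sin(ang)))))
    },
    octagon = {
      ang <- pi / 8 + (0:7) * pi / 4
      .polygon_pts(unique(cbind(round(r * cos(ang)), round(r * sin(ang)))))
    },
    star = {
      ri <- max(1L, as.integer(ceiling(r / 2)))
      .polygon_pts(rbind(c(0, -r), c(ri, -ri), c(r, 0), c(ri, ri),
                         c(0, r), c(-ri, ri), c(-r, 0), c(-ri, -ri)))
    },
    stop("unknown shape class: ", shape)
  )
}

# place pixel offsets at (cx, cy) on img additively, clipping intensity at 1;
# errors if any pixel falls outside the canvas.
.place <- function(img, cx, cy, pts, fg) {
  xs <- pts[, 1] + cx; ys <- pts[, 2] + cy
  if (any(xs < 1 | xs > ncol(img) | ys < 1 | ys > nrow(img)))
    stop(sprintf("geometry exceeds canvas (%dx%d): pixels at x in [%d,%d], y in [%d,%d]",
                 nrow(img), ncol(img), min(xs), max(xs), min(ys), max(ys)))
  idx <- cbind(ys, xs)
  img[idx] <- pmin(1, img[idx] + fg)
  img
}

.blank <- function(cfg) matrix(0, cfg$height, cfg$width)
.center <- function(cfg) c(x = (cfg$width + 1L) %/% 2L, y = (cfg$height + 1L) %/% 2L)

# vernier pixel offsets around (0,0): two 1-px-wide vertical bars, horizontal
# offset split symmetrically so left/right are exact mirrors about x = 0.
.vernier_pts <- function(direction, length, gap, offset) {
  q1 <- offset %/% 2L; q2 <- offset - q1
  gtop <- -(gap %/% 2L)               # first gap row
  top_rows <- (gtop - length):(gtop - 1L)
  bot_rows <- (gtop + gap):(gtop + gap + length - 1L)
  if (direction == "right") {
    xt <- -q1; xb <- q2
  } else if (direction == "left") {
    xt <- q1; xb <- -q2
  } else stop("offset_direction must be 'left' or 'right'")
  rbind(cbind(xt, top_rows), cbind(xb, bot_rows))
}

# ---- renderers -------------------------------------------------------------

#' Render a vernier target
#'
#' Two one-pixel-wide vertical bars separated by a small vertical gap, with
#' the lower bar horizontally offset in the requested direction. Left and
#' right renders at the same centre are exact horizontal mirror images.
#'
#' @param offset_direction "left" or "right".
#' @param config A [stim_config()].
#' @param offset_px Offset magnitude in pixels (default from config).
#' @param at Integer `(x, y)` centre; defaults to the canvas centre.
#' @return A [stimulus_frame()] with `shape_class = "vernier"`.
#' @export
render_vernier <- function(offset_direction, config = stim_config(),
                           offset_px = config$vernier_offset_px,
                           at = .center(config)) {
  if (!offset_direction %in% c("left", "right"))
    stop("offset_direction must be 'left' or 'right'")
  pts <- .vernier_pts(offset_direction, config$vernier_length,
                      config$vernier_gap, as.integer(offset_px))
  img <- .place(.blank(config), at[1], at[2], pts, config$fg)
  stimulus_frame(img, "vernier", 1L, offset_direction, at[1], at[2])
}

#' Render a horizontal group of identical shapes
#'
#' @param shape_class One of the experiment-1 flanker classes in
#'   `config$shapes`.
#' @param n_repetitions 1, 3 or 5 shapes.
#' @param spacing Pixel gap between adjacent shape bounding boxes.
#' @param config A [stim_config()].
#' @param at Group centre `(x, y)`; defaults to the canvas centre.
#' @return A [stimulus_frame()].
#' @export
render_shape_group <- function(shape_class, n_repetitions,
                               spacing = config$spacing,
                               config = stim_config(),
                               at = .center(config)) {
  if (!shape_class %in% config$shapes)
    stop("unknown shape class: ", shape_class)
  if (!n_repetitions %in% c(1L, 3L, 5L))
    stop("n_repetitions must be 1, 3 or 5")
  s <- config$shape_size
  pitch <- s + spacing
  total_w <- n_repetitions * s + (n_repetitions - 1L) * spacing
  if (total_w > config$width)
    stop(sprintf("shape group (%d px) wider than canvas (%d px)", total_w, config$width))
  pts <- .shape_pts(shape_class, s)
  img <- .blank(config)
  offs <- (seq_len(n_repetitions) - (n_repetitions + 1L) / 2L) * pitch
  for (o in offs) img <- .place(img, at[1] + o, at[2], pts, config$fg)
  stimulus_frame(img, shape_class, n_repetitions, "none", at[1], at[2])
}

# visible wireframe edges of a perspective cuboid, as a list of pixel-offset
# matrices (one per edge), mutually disjoint by construction. `facing` is the
# side on which the facing partner sits: the obliques recede away from it.
# Offsets are relative to the centre of the front face.
.cuboid_segments <- function(width, height, depth, facing = c("right", "left")) {
  facing <- match.arg(facing)
  hw <- (width - 1L) %/% 2L; hh <- (height - 1L) %/% 2L
  x0 <- -hw; x1 <- width - 1L - hw; y0 <- -hh; y1 <- height - 1L - hh
  d <- depth
  sgn <- if (facing == "right") -1L else 1L  # obliques recede away from partner
  seg <- list()
  half <- function(m) m[-nrow(m), , drop = FALSE]
  # front rectangle (4 half-open edges)
  seg$front_top    <- half(.bres(x0, y0, x1, y0))
  seg$front_right  <- half(.bres(x1, y0, x1, y1))
  seg$front_bottom <- half(.bres(x1, y1, x0, y1))
  seg$front_left   <- half(.bres(x0, y1, x0, y0))
  # three visible obliques (interiors only; endpoints belong to rectangles)
  interior <- function(m) if (nrow(m) > 2) m[-c(1, nrow(m)), , drop = FALSE] else m[0, , drop = FALSE]
  bx0 <- x0 + sgn * d; bx1 <- x1 + sgn * d; by0 <- y0 - d; by1 <- y1 - d
  seg$obl_tl <- interior(.bres(x0, y0, bx0, by0))
  seg$obl_tr <- interior(.bres(x1, y0, bx1, by0))
  outer_x <- if (sgn < 0) x0 else x1
  seg$obl_bo <- interior(.bres(outer_x, y1, outer_x + sgn * d, by1))
  # visible back edges: top edge and the outer vertical edge
  seg$back_top   <- .bres(bx0, by0, bx1, by0)
  seg$back_outer <- {
    bx <- if (sgn < 0) bx0 else bx1
    m <- .bres(bx, by0, bx, by1)
    m[-1, , drop = FALSE] # corner already in back_top
  }
  # enforce pairwise disjointness (robust to degenerate geometries)
  seen <- matrix(integer(0), 0, 2)
  for (nm in names(seg)) {
    m <- seg[[nm]]
    if (nrow(m) == 0) next
    keep <- !(paste(m[, 1], m[, 2]) %in% paste(seen[, 1], seen[, 2]))
    seg[[nm]] <- m[keep, , drop = FALSE]
    seen <- rbind(seen, seg[[nm]])
  }
  seg
}

#' Specification of one experiment-2 training stimulus
#'
#' @param kind "vernier", "line_group", "cuboid_pair" or
#'   "scrambled_cuboid_pair".
#' @param line_count Number of lines in a line group (2, 4 or 6 by default).
#' @param pair_spacing Gap in pixels between the facing elements of a cuboid
#'   (or scrambled-cuboid) pair, or between adjacent lines; must lie in
#'   `[1, 6]`.
#' @return An object of class `exp2_shape_spec`.
#' @export
exp2_shape_spec <- function(kind, line_count = 2L, pair_spacing = 2L) {
  kinds <- c("vernier", "line_group", "cuboid_pair", "scrambled_cuboid_pair")
  if (!kind %in% kinds) stop("invalid kind: ", kind)
  if (pair_spacing < 1 || pair_spacing > 6)
    stop("pair_spacing must be in [1, 6], got ", pair_spacing)
  structure(list(kind = kind, line_count = as.integer(line_count),
                 pair_spacing = as.integer(pair_spacing)),
            class = "exp2_shape_spec")
}

#' Render an experiment-2 stimulus
#'
#' Line groups are evenly spaced one-pixel vertical lines; cuboid pairs are
#' two mirror-image perspective cuboids whose innermost (front) edges are the
#' flanking lines of the line condition; scrambled cuboids contain exactly
#' the same line segments, translated to random non-overlapping positions
#' inside the same bounding region (so the pixel count is unchanged).
#'
#' @param spec An [exp2_shape_spec()].
#' @param config A `stim_config` for experiment 2.
#' @param at Centre `(x, y)`.
#' @return A [stimulus_frame()].
#' @export
render_exp2_stimulus <- function(spec, config = stim_config(experiment = 2),
                                 at = .center(config)) {
  stopifnot(inherits(spec, "exp2_shape_spec"))
  cx <- at[1]; cy <- at[2]
  ll <- config$line_length
  hh <- (ll - 1L) %/% 2L
  line_pts <- cbind(0L, (-hh):(ll - 1L - hh))
  img <- .blank(config)
  if (spec$kind == "vernier") {
    return(render_vernier(sample(c("left", "right"), 1), config, at = at))
  } else if (spec$kind == "line_group") {
    k <- spec$line_count
    pitch <- 1L + spec$pair_spacing
    offs <- round((seq_len(k) - (k + 1) / 2) * pitch)
    for (o in offs) img <- .place(img, cx + o, cy, line_pts, config$fg)
    return(stimulus_frame(img, "lines", k, "none", cx, cy))
  }
  # cuboid pair: innermost front edges at +- ceil(spacing/2) from centre
  gap <- spec$pair_spacing
  w <- config$cuboid_width
  inner_l <- cx - ((gap + 1L) %/% 2L)
  inner_r <- inner_l + gap + 1L
  segs_l <- .cuboid_segments(w, ll, config$cuboid_depth, facing = "right")
  segs_r <- .cuboid_segments(w, ll, config$cuboid_depth, facing = "left")
  # front-face centres such that the inner front edge sits at inner_l/inner_r
  hw <- (w - 1L) %/% 2L
  cl <- inner_l - (w - 1L - hw)  # left cuboid: inner edge is its right edge
  cr <- inner_r + hw             # right cuboid: inner edge is its left edge
  if (spec$kind == "cuboid_pair") {
    for (m in segs_l) if (nrow(m)) img <- .place(img, cl, cy, m, config$fg)
    for (m in segs_r) if (nrow(m)) img <- .place(img, cr, cy, m, config$fg)
    return(stimulus_frame(img, "cuboids", 2L, "none", cx, cy))
  }
  # scrambled: translate each segment randomly within its cuboid's region
  # (bounding box plus a 2-px margin), rejecting overlaps — tracked in
  # absolute canvas coordinates so the two cuboids cannot collide either —
  # and clipping. Pixel count is preserved exactly. If an arrangement jams
  # (rejection sampling can corner itself), the whole arrangement is redrawn.
  d <- config$cuboid_depth
  for (attempt in 1:50) {
    occupied <- matrix(integer(0), 0, 2)
    img_try <- img
    ok_all <- TRUE
    for (grp in list(list(segs = segs_l, c0 = cl), list(segs = segs_r, c0 = cr))) {
      if (!ok_all) break
      for (m in grp$segs) {
        if (nrow(m) == 0) next
        placed <- FALSE
        for (try in 1:400) {
          sh <- c(sample(-(hw + d + 2):(hw + d + 2), 1),
                  sample(-(d + 2):(d + 2), 1))
          xs <- m[, 1] + sh[1] + grp$c0; ys <- m[, 2] + sh[2] + cy
          ok_canvas <- all(xs >= 1 & xs <= config$width &
                             ys >= 1 & ys <= config$height)
          ok_free <- !any(paste(xs, ys) %in% paste(occupied[, 1], occupied[, 2]))
          if (ok_canvas && ok_free) {
            occupied <- rbind(occupied, cbind(xs, ys))
            img_try[cbind(ys, xs)] <- pmin(1, img_try[cbind(ys, xs)] + config$fg)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok_all <- FALSE; break }
      }
    }
    if (ok_all) return(stimulus_frame(img_try, "scrambled_cuboids", 2L, "none",
                                      cx, cy))
  }
  stop("could not place scrambled cuboid segments without overlap")
}

# ---- test conditions -------------------------------------------------------

#' Construct a test condition
#'
#' @param name Condition identifier.
#' @param flanker_layout Character vector of flanker shape classes from left
#'   to right (length 0 for no flankers; experiment 2 uses "lines" or
#'   "cuboids" for a flanker pair).
#' @param vernier_placement "inside" (centred on the central flanker),
#'   "outside" (above the flanker bounding box) or "alone".
#' @param baseline Name of the matched central-flanker-alone baseline
#'   condition, or `NA`.
#' @return An object of class `test_condition`.
#' @export
test_condition <- function(name, flanker_layout = character(),
                           vernier_placement = c("inside", "outside", "alone"),
                           baseline = NA_character_) {
  vernier_placement <- match.arg(vernier_placement)
  if (vernier_placement == "alone" && length(flanker_layout) > 0)
    stop("'alone' layouts must contain no flankers")
  structure(list(name = name, flanker_layout = flanker_layout,
                 vernier_placement = vernier_placement, baseline = baseline),
            class = "test_condition")
}

#' Compose a test stimulus from a vernier frame and a condition
#'
#' The vernier's drawn pixels are translated so that, for "inside", the
#' vernier centre coincides with the central flanker's centre; for
#' "outside", the vernier sits above the flanker configuration's bounding
#' box; "alone" returns the vernier frame unchanged. Flankers are drawn
#' additively; a flanker pixel landing on a vernier pixel is an error (it
#' would corrupt the target).
#'
#' @param vernier A vernier [stimulus_frame()].
#' @param condition A [test_condition()].
#' @param config The `stim_config` used for the flankers.
#' @return A composed [stimulus_frame()] carrying the vernier offset label.
#' @export
compose_test_stimulus <- function(vernier, condition, config = stim_config()) {
  stopifnot(inherits(vernier, "stimulus_frame"), inherits(condition, "test_condition"))
  if (condition$vernier_placement == "alone") {
    out <- vernier
    out$condition <- condition$name
    return(out)
  }
  ctr <- .center(config)
  vpix <- which(vernier$image > 0, arr.ind = TRUE) # (row=y, col=x)
  layout <- condition$flanker_layout
  img <- .blank(config)
  # draw flankers
  if (config$experiment == 1 || !layout[1] %in% c("lines", "cuboids")) {
    s <- config$shape_size
    pitch <- s + config$spacing
    n <- length(layout)
    offs <- (seq_len(n) - (n + 1) / 2) * pitch
    for (i in seq_len(n))
      img <- .place(img, ctr[1] + offs[i], ctr[2], .shape_pts(layout[i], s), config$fg)
    bb_top <- ctr[2] - (s - 1L) %/% 2L
  } else {
    ll <- config$line_length; hh <- (ll - 1L) %/% 2L
    xs_inner <- c(ctr[1] - config$flank_dist, ctr[1] + config$flank_dist)
    if (layout[1] == "lines") {
      line_pts <- cbind(0L, (-hh):(ll - 1L - hh))
      for (x in xs_inner) img <- .place(img, x, ctr[2], line_pts, config$fg)
    } else {
      w <- config$cuboid_width; hw <- (w - 1L) %/% 2L
      segs_l <- .cuboid_segments(w, ll, config$cuboid_depth, "right")
      segs_r <- .cuboid_segments(w, ll, config$cuboid_depth, "left")
      cl <- xs_inner[1] - (w - 1L - hw); cr <- xs_inner[2] + hw
      for (m in segs_l) if (nrow(m)) img <- .place(img, cl, ctr[2], m, config$fg)
      for (m in segs_r) if (nrow(m)) img <- .place(img, cr, ctr[2], m, config$fg)
    }
    bb_top <- ctr[2] - hh - config$cuboid_depth
  }
  # place the vernier
  if (condition$vernier_placement == "inside") {
    dx <- ctr[1] - vernier$x; dy <- ctr[2] - vernier$y
  } else { # outside: directly above the configuration bounding box
    dx <- ctr[1] - vernier$x
    dy <- (bb_top - 1L) - max(vpix[, 1])
  }
  ys <- vpix[, 1] + dy; xs <- vpix[, 2] + dx
  if (any(xs < 1 | xs > config$width | ys < 1 | ys > config$height))
    stop("vernier placement exceeds canvas")
  idx <- cbind(ys, xs)
  if (any(img[idx] > 0))
    stop("flanker pixels overlap the vernier target in condition ", condition$name)
  img[idx] <- pmin(1, img[idx] + vernier$image[vpix])
  stimulus_frame(img,
                 shape_class = if (length(layout)) layout[(length(layout) + 1) %/% 2] else "vernier",
                 n_repetitions = length(layout),
                 vernier_offset = vernier$vernier_offset,
                 x = vernier$x + dx, y = vernier$y + dy,
                 condition = condition$name)
}

#' Build the test battery for one experiment
#'
#' Experiment 1: vernier-alone, plus for every flanker shape a
#' central-flanker-alone baseline, a 5-identical uncrowding configuration and
#' 5-alternating configurations, each with a matching vernier-outside
#' control. Experiment 2: vernier-alone, a line-pair and a cuboid-pair
#' condition.
#'
#' @param experiment 1 or 2.
#' @param shapes Flanker shapes to include (experiment 1); defaults to all
#'   six.
#' @param alternating_pairs Two-column character matrix of (central, other)
#'   shape pairs for alternating configurations; defaults to consecutive
#'   pairs of `shapes`.
#' @param outside_controls Include vernier-outside control conditions.
#' @return A list of [test_condition()] objects.
#' @export
build_test_battery <- function(experiment = 1,
                               shapes = stim_config()$shapes,
                               alternating_pairs = NULL,
                               outside_controls = TRUE) {
  if (experiment == 2) {
    return(list(
      test_condition("vernier_alone", character(), "alone"),
      test_condition("lines", "lines", "inside", baseline = "vernier_alone"),
      test_condition("cuboids", "cuboids", "inside", baseline = "vernier_alone")
    ))
  }
  if (is.null(alternating_pairs)) {
    nxt <- c(shapes[-1], shapes[1])
    alternating_pairs <- cbind(shapes, nxt)
  }
  conds <- list(test_condition("vernier_alone", character(), "alone"))
  add <- function(conds, name, layout, baseline) {
    conds <- c(conds, list(test_condition(name, layout, "inside", baseline)))
    if (outside_controls)
      conds <- c(conds, list(test_condition(paste0(name, "_outside"), layout,
                                            "outside", "vernier_alone")))
    conds
  }
  for (s in shapes)
    conds <- add(conds, paste0(s, "_1"), s, baseline = paste0(s, "_1"))
  for (s in shapes)
    conds <- add(conds, paste0(s, "_5same"), rep(s, 5), baseline = paste0(s, "_1"))
  if (nrow(alternating_pairs) > 0)
    for (i in seq_len(nrow(alternating_pairs))) {
      a <- alternating_pairs[i, 1]; b <- alternating_pairs[i, 2]
      if (a == b) next
      conds <- add(conds, paste0(a, "_", b, "_5alt"), c(a, b, a, b, a),
                   baseline = paste0(a, "_1"))
    }
  conds
}

# ---- augmentation ----------------------------------------------------------

#' Augmentation configuration
#'
#' Additive Gaussian pixel noise with zero mean and a per-frame standard
#' deviation drawn uniformly from `noise_sd_range`, followed by a brightness
#' shift and a contrast scaling applied in a random order, then clipping to
#' `[0, 1]`.
#'
#' @param noise_mean Fixed at 0.
#' @param noise_sd_range Uniform draw interval for the noise sd.
#' @param brightness_shift_range Interval for the additive shift.
#' @param contrast_factor_range Interval (positive) for the multiplicative
#'   contrast factor.
#' @return An object of class `aug_config`.
#' @export
aug_config <- function(noise_mean = 0, noise_sd_range = c(0, 0.2),
                       brightness_shift_range = c(-0.1, 0.1),
                       contrast_factor_range = c(0.6, 1.2)) {
  stopifnot(noise_mean == 0, noise_sd_range[1] >= 0,
            contrast_factor_range[1] >= 0,
            diff(noise_sd_range) >= 0, diff(contrast_factor_range) >= 0)
  structure(list(noise_mean = noise_mean, noise_sd_range = noise_sd_range,
                 brightness_shift_range = brightness_shift_range,
                 contrast_factor_range = contrast_factor_range),
            class = "aug_config")
}

#' Apply noise/contrast augmentation to a frame
#'
#' @param frame A [stimulus_frame()].
#' @param config An [aug_config()].
#' @return The frame with augmented image; labels unchanged. Uses R's global
#'   RNG; seed for reproducibility.
#' @export
augment_frame <- function(frame, config = aug_config()) {
  img <- frame$image
  sd <- stats::runif(1, config$noise_sd_range[1], config$noise_sd_range[2])
  if (sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, sd), nrow(img))
  shift <- stats::runif(1, config$brightness_shift_range[1],
                        config$brightness_shift_range[2])
  fac <- stats::runif(1, config$contrast_factor_range[1],
                      config$contrast_factor_range[2])
  if (stats::runif(1) < 0.5) img <- (img + shift) * fac else img <- img * fac + shift
  img <- pmin(pmax(img, 0), 1)
  frame$image <- img
  frame
}

# ---- training sets ---------------------------------------------------------

#' Generate a training set of single-stimulus frames
#'
#' Each frame contains either a lone vernier or a lone shape group; verniers
#' and flanker shapes are never combined, so the network is never exposed to
#' (un)crowding stimuli during training. Classes are sampled uniformly.
#'
#' @param experiment 1 or 2.
#' @param n_frames Number of frames.
#' @param config A [stim_config()] for the experiment.
#' @param aug An [aug_config()], or `NULL` for clean frames.
#' @param seed Optional integer seed.
#' @return List of [stimulus_frame()] objects.
#' @export
build_training_set <- function(experiment = 1, n_frames,
                               config = stim_config(experiment = experiment),
                               aug = aug_config(), seed = NULL) {
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- training_classes(experiment, config)
  ctr <- .center(config)
  jx <- config$jitter[1]; jy <- config$jitter[2]
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    at <- ctr
    cls <- sample(classes, 1)
    f <- if (cls == "vernier") {
      render_vernier(sample(c("left", "right"), 1), config,
                     offset_px = sample(config$train_offsets, 1), at = at)
    } else if (experiment == 1) {
      render_shape_group(cls, sample(c(1L, 3L, 5L), 1), config$spacing, config, at = at)
    } else {
      spec <- switch(cls,
        lines = exp2_shape_spec("line_group",
                                line_count = sample(config$line_group_sizes, 1),
                                pair_spacing = sample(config$line_spacing_range[1]:config$line_spacing_range[2], 1)),
        cuboids = exp2_shape_spec("cuboid_pair",
                                  pair_spacing = sample(config$pair_spacing_range[1]:config$pair_spacing_range[2], 1)),
        scrambled_cuboids = exp2_shape_spec("scrambled_cuboid_pair",
                                            pair_spacing = sample(config$pair_spacing_range[1]:config$pair_spacing_range[2], 1)))
      render_exp2_stimulus(spec, config, at = at)
    }
    f <- .jitter_frame(f, jx, jy)
    if (!is.null(aug)) f <- augment_frame(f, aug)
    frames[[i]] <- f
  }
  frames
}

# translate a clean frame by a random jitter, clamped so no pixel leaves the
# canvas ("roughly centered in the middle of the image")
.jitter_frame <- function(frame, jx, jy) {
  pix <- which(frame$image > 0, arr.ind = TRUE)
  lo_x <- -min(pix[, 2]) + 1L; hi_x <- ncol(frame$image) - max(pix[, 2])
  lo_y <- -min(pix[, 1]) + 1L; hi_y <- nrow(frame$image) - max(pix[, 1])
  dx <- sample(max(-jx, lo_x):min(jx, hi_x), 1)
  dy <- sample(max(-jy, lo_y):min(jy, hi_y), 1)
  if (dx == 0 && dy == 0) return(frame)
  img <- matrix(0, nrow(frame$image), ncol(frame$image))
  img[cbind(pix[, 1] + dy, pix[, 2] + dx)] <- frame$image[pix]
  frame$image <- img
  frame$x <- frame$x + dx; frame$y <- frame$y + dy
  frame
}

#' Class set used during training
#' @param experiment 1 or 2.
#' @param config A `stim_config`.
#' @return Character vector: vernier plus the experiment's shape classes.
#' @export
training_classes <- function(experiment = 1, config = stim_config(experiment = experiment)) {
  if (experiment == 1) c("vernier", config$shapes)
  else c("vernier", "lines", "cuboids", "scrambled_cuboids")
}

# ---- plain-text image archive ---------------------------------------------

#' Write a stimulus set as plain-text PGM images plus a CSV label table
#'
#' @param frames List of [stimulus_frame()] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path of the label table.
#' @export
write_stimulus_set <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(frame_id = sprintf("frame_%05d", seq_along(frames)),
                       shape_class = vapply(frames, `[[`, "", "shape_class"),
                       n_repetitions = vapply(frames, `[[`, 1L, "n_repetitions"),
                       vernier_offset = vapply(frames, `[[`, "", "vernier_offset"),
                       x = vapply(frames, `[[`, 1L, "x"),
                       y = vapply(frames, `[[`, 1L, "y"),
                       condition_name = vapply(frames, function(f)
                         if (is.na(f$condition)) "" else f$condition, ""))
  for (i in seq_along(frames)) {
    img <- round(frames[[i]]$image * 255)
    con <- file.path(dir, paste0(labels$frame_id[i], ".pgm"))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255",
                 apply(img, 1, paste, collapse = " ")), con)
  }
  path <- file.path(dir, "labels.csv")
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Read one plain-text PGM image back as a matrix in `[0, 1]`
#' @param path Path to a P2 PGM file written by [write_stimulus_set()].
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  toks <- as.numeric(unlist(strsplit(paste(lines[-1], collapse = " "), "[[:space:]]+")))
  toks <- toks[!is.na(toks)]
  w <- toks[1]; h <- toks[2]; maxv <- toks[3]
  matrix(toks[-(1:3)], nrow = h, ncol = w, byrow = TRUE) / maxv
}
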