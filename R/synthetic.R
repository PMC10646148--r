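## Synthetic two-channel acquisition generator with exact graph ground truth.
##
## Emulates confocal fields of cultured spinal motor neurons: a DAPI channel
## with round nuclei and a Map2-like marker channel with bright somata and
## tree-shaped neurites 1-3 px wide. Neurite trees grow by stochastic
## segment elongation (exponential segment lengths, small angular jitter,
## bifurcation with a tunable per-step probability), which gives a single
## density knob mapping onto wild-type vs. knockout network phenotypes.
## Every acquisition carries its true neurite graph (soma roots, junctions,
## endpoints, polyline edges) and analytically computed morphometry, so the
## measurement stages can be tested against known truth.

#' Parameters of the synthetic acquisition generator
#'
#' Defaults emulate the acquisition geometry of the motivating experiments
#' (212.3 um fields at 0.207 um/px, trimmed to 1024 px = 211.968 um for
#' convenience) with a moderately dense field of mature motor neurons.
#' Intensity levels are implementer-chosen 16-bit ADU values (no published
#' intensity statistics exist for the original images).
#'
#' @param field_size_um Field side length in micrometers. The raster is
#'   `floor(field_size_um / pixel_size_um)` pixels per side.
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @param n_cells Number of cells placed in the field (non-overlapping).
#' @param nucleus_diameter_um_range `(min, max)` nucleus diameter in um.
#'   The default floor (9 um) stays above the 8.3 um equivalent diameter
#'   implied by the 20 px small-object cutoff of the nuclei mask, so the
#'   cutoff removes debris, never nuclei.
#' @param neurites_per_cell_range `(min, max)` primary neurites per cell.
#' @param branching_prob Bifurcation probability per elongation step, in
#'   `[0, 1]`; the density knob distinguishing WT from KO-like networks.
#' @param mean_segment_len_um Mean of the exponential elongation-step
#'   length, micrometers.
#' @param neurite_width_px_range `(min, max)` rendered neurite width in
#'   pixels, within `[1, 5]`.
#' @param signal_level Peak neurite intensity in ADU.
#' @param background_level Additive background in ADU.
#' @param noise_model One of `"none"`, `"gaussian"` (additive read noise of
#'   s.d. `noise_sd`) or `"poisson"` (shot noise at `photons_per_adu`
#'   photons per ADU, plus the Gaussian read noise).
#' @param noise_sd Gaussian read-noise standard deviation, ADU.
#' @param photons_per_adu Photon conversion for the shot-noise model.
#' @param seed Integer seed; fixes every random choice of the generator.
#' @param bit_depth Output bit depth, 8 or 16 (default 16; confocal data
#'   are typically >= 12-bit).
#' @param max_branch_depth Maximum bifurcation depth of a neurite tree.
#' @param step_stop_prob Per-step probability that a growing tip
#'   terminates (controls neurite extent).
#' @param angle_jitter_sd Angular jitter per elongation step, radians.
#' @param branch_half_angle Half-angle between daughter branches, radians.
#' @param soma_brightness Soma intensity relative to `signal_level`
#'   (somata render brighter than neurites).
#' @param falloff_length_um Length scale of the exponential intensity
#'   falloff along a neurite (arc distance from the soma).
#' @param psf_sigma_um Gaussian stand-in for the optical point-spread
#'   function, applied to both channels before noise; 0 disables. The
#'   default 0.25 um matches the lateral resolution of a high-NA confocal.
#' @param soma_clip_margin_um Margin added to the nucleus radius when the
#'   ground-truth network is clipped around each soma, mirroring the 5 px
#'   soma-mask expansion of the measurement stage (default
#'   `5 * pixel_size_um`).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(field_size_um = 211.968,
                             pixel_size_um = 0.207,
                             n_cells = 10L,
                             nucleus_diameter_um_range = c(9, 15),
                             neurites_per_cell_range = c(2L, 4L),
                             branching_prob = 0.22,
                             mean_segment_len_um = 14,
                             neurite_width_px_range = c(1, 3),
                             signal_level = 8000,
                             background_level = 400,
                             noise_model = c("poisson", "gaussian", "none"),
                             noise_sd = 60,
                             photons_per_adu = 0.05,
                             seed = 1L,
                             bit_depth = 16L,
                             max_branch_depth = 5L,
                             step_stop_prob = 0.2,
                             angle_jitter_sd = 0.25,
                             branch_half_angle = 0.6,
                             soma_brightness = 1.3,
                             falloff_length_um = 150,
                             psf_sigma_um = 0.25,
                             soma_clip_margin_um = 5 * pixel_size_um) {
  noise_model <- match.arg(noise_model)
  p <- list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
            n_cells = as.integer(n_cells),
            nucleus_diameter_um_range = nucleus_diameter_um_range,
            neurites_per_cell_range = as.integer(neurites_per_cell_range),
            branching_prob = branching_prob,
            mean_segment_len_um = mean_segment_len_um,
            neurite_width_px_range = neurite_width_px_range,
            signal_level = signal_level, background_level = background_level,
            noise_model = noise_model, noise_sd = noise_sd,
            photons_per_adu = photons_per_adu, seed = as.integer(seed),
            bit_depth = as.integer(bit_depth),
            max_branch_depth = as.integer(max_branch_depth),
            step_stop_prob = step_stop_prob,
            angle_jitter_sd = angle_jitter_sd,
            branch_half_angle = branch_half_angle,
            soma_brightness = soma_brightness,
            falloff_length_um = falloff_length_um,
            psf_sigma_um = psf_sigma_um,
            soma_clip_margin_um = soma_clip_margin_um)
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  stopifnot(p$field_size_um > 0, p$pixel_size_um > 0,
            p$n_cells >= 0,
            p$branching_prob >= 0, p$branching_prob <= 1,
            p$mean_segment_len_um > 0,
            p$signal_level > 0, p$background_level >= 0,
            p$bit_depth %in% c(8L, 16L),
            p$step_stop_prob >= 0, p$step_stop_prob <= 1,
            p$psf_sigma_um >= 0)
  rng <- function(r, what, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop(sprintf("invalid %s range", what))
  }
  rng(p$nucleus_diameter_um_range, "nucleus diameter", lo = 0)
  rng(p$neurites_per_cell_range, "neurites per cell", lo = 0)
  rng(p$neurite_width_px_range, "neurite width", lo = 1, hi = 5)
  invisible(p)
}

field_pixels <- function(p) as.integer(floor(p$field_size_um / p$pixel_size_um))

# --- cell placement -------------------------------------------------------

place_cells <- function(p, field_um) {
  n <- p$n_cells
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)))
  xs <- ys <- rs <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(paste0("field of %.1f um cannot hold %d non-overlapping ",
                          "cells of diameter %.1f-%.1f um"),
                   field_um, n,
                   p$nucleus_diameter_um_range[1],
                   p$nucleus_diameter_um_range[2]))
    r <- stats::runif(1, p$nucleus_diameter_um_range[1],
                      p$nucleus_diameter_um_range[2]) / 2
    margin <- r + 1
    if (2 * margin >= field_um)
      stop(sprintf("field of %.1f um is smaller than one cell", field_um))
    x <- stats::runif(1, margin, field_um - margin)
    y <- stats::runif(1, margin, field_um - margin)
    if (placed > 0L) {
      dd <- sqrt((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2)
      if (any(dd < rs[seq_len(placed)] + r + 2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y; rs[placed] <- r
  }
  data.frame(x = xs, y = ys, r = rs)
}

# --- neurite tree growth --------------------------------------------------

# Grows all trees of one acquisition. Returns nodes (id, x, y, kind) and a
# list of edges (from, to, poly [n x 2 um], cell, width_px, arc0_um).
grow_forest <- function(p, cells, field_um) {
  nodes <- list(); edges <- list()
  n_nodes <- 0L
  add_node <- function(x, y, kind) {
    n_nodes <<- n_nodes + 1L
    nodes[[n_nodes]] <<- list(id = n_nodes, x = x, y = y, kind = kind)
    n_nodes
  }
  clip_to_field <- function(a, b) {
    # first intersection of segment a->b with the field border; b outside
    d <- b - a
    ts <- c(if (d[1] < 0) (0 - a[1]) / d[1] else if (d[1] > 0) (field_um - a[1]) / d[1] else Inf,
            if (d[2] < 0) (0 - a[2]) / d[2] else if (d[2] > 0) (field_um - a[2]) / d[2] else Inf)
    t <- max(min(ts), 0)
    a + t * d
  }
  for (ci in seq_len(nrow(cells))) {
    cx <- cells$x[ci]; cy <- cells$y[ci]; cr <- cells$r[ci]
    k <- if (p$neurites_per_cell_range[1] == p$neurites_per_cell_range[2])
      p$neurites_per_cell_range[1]
    else sample(seq(p$neurites_per_cell_range[1],
                    p$neurites_per_cell_range[2]), 1L)
    if (k == 0L) next
    base <- stats::runif(1, 0, 2 * pi)
    for (ni in seq_len(k)) {
      ang <- base + (ni - 1) * 2 * pi / k + stats::rnorm(1, 0, 0.2)
      sx <- cx + cr * cos(ang); sy <- cy + cr * sin(ang)
      if (sx <= 0 || sx >= field_um || sy <= 0 || sy >= field_um) next
      root <- add_node(sx, sy, "soma-root")
      width <- stats::runif(1, p$neurite_width_px_range[1],
                            p$neurite_width_px_range[2])
      stack <- list(list(x = sx, y = sy, dir = ang, depth = 0L,
                         from = root, arc0 = 0))
      while (length(stack)) {
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        poly <- matrix(c(st$x, st$y), ncol = 2)
        pos <- c(st$x, st$y); dir <- st$dir
        arc <- st$arc0
        terminal <- NULL
        for (step in 1:60) {
          len <- min(max(stats::rexp(1, 1 / p$mean_segment_len_um), 1),
                     3 * p$mean_segment_len_um)
          dir <- dir + stats::rnorm(1, 0, p$angle_jitter_sd)
          q <- pos + len * c(cos(dir), sin(dir))
          if (q[1] <= 0 || q[1] >= field_um || q[2] <= 0 || q[2] >= field_um) {
            q <- clip_to_field(pos, q)
            poly <- rbind(poly, q)
            arc <- arc + sqrt(sum((q - pos)^2))
            terminal <- list(kind = "endpoint", x = q[1], y = q[2])
            break
          }
          poly <- rbind(poly, q)
          arc <- arc + len
          pos <- q
          u <- stats::runif(1)
          if (st$depth < p$max_branch_depth && u < p$branching_prob) {
            terminal <- list(kind = "junction", x = q[1], y = q[2])
            break
          }
          if (u < p$branching_prob + p$step_stop_prob * (1 - p$branching_prob) ||
              step == 60L) {
            terminal <- list(kind = "endpoint", x = q[1], y = q[2])
            break
          }
        }
        if (is.null(terminal) || nrow(poly) < 2) next
        to <- add_node(terminal$x, terminal$y, terminal$kind)
        edges[[length(edges) + 1L]] <-
          list(from = st$from, to = to, poly = poly, cell = ci,
               width_px = width, arc0_um = st$arc0)
        if (terminal$kind == "junction") {
          spread <- p$branch_half_angle * stats::runif(2, 0.7, 1.3)
          for (s in c(-1, 1)) {
            stack[[length(stack) + 1L]] <-
              list(x = terminal$x, y = terminal$y,
                   dir = dir + s * spread[(s + 3) / 2],
                   depth = st$depth + 1L, from = to, arc0 = arc)
          }
        }
      }
    }
  }
  nodes_df <- if (n_nodes)
    data.frame(id = vapply(nodes, `[[`, 0L, "id"),
               x = vapply(nodes, `[[`, 0, "x"),
               y = vapply(nodes, `[[`, 0, "y"),
               kind = vapply(nodes, `[[`, "", "kind"),
               stringsAsFactors = FALSE)
  else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                  kind = character(0))
  list(nodes = nodes_df, edges = edges)
}

# degree-based re-classification: a "junction" node that received no
# daughters (e.g. both daughters died at the border immediately) is really
# an endpoint; computed from edge incidence.
reclassify_nodes <- function(nodes, edges) {
  if (!nrow(nodes)) return(nodes)
  deg <- integer(nrow(nodes))
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  fix <- nodes$kind == "junction" & deg < 3L
  nodes$kind[fix] <- "endpoint"
  nodes
}

# --- analytic ground-truth morphometry ------------------------------------
#
# The metrics a perfect measurement of the rendered image would report are
# those of the APPARENT planar network, not of the biological forest: the
# neurite mask erases everything inside the expanded soma disks, and two
# neurites that cross in the 2-D projection form a visible four-way
# junction. The ground-truth graph is therefore the forest (i) clipped
# against the soma disks grown by the downstream mask-expansion margin and
# (ii) planarized at every inter-polyline crossing.

# union of the (t0, t1) sub-intervals of segment a->b lying inside any disk
segment_inside_intervals <- function(a, b, cx, cy, r) {
  d <- b - a
  ivals <- NULL
  for (i in seq_along(cx)) {
    f <- a - c(cx[i], cy[i])
    A <- sum(d^2); B <- 2 * sum(f * d); C <- sum(f^2) - r[i]^2
    if (A == 0) next
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next
    sq <- sqrt(disc)
    t0 <- max((-B - sq) / (2 * A), 0)
    t1 <- min((-B + sq) / (2 * A), 1)
    if (t1 > t0) ivals <- rbind(ivals, c(t0, t1))
  }
  if (is.null(ivals)) return(NULL)
  ivals <- ivals[order(ivals[, 1]), , drop = FALSE]
  merged <- ivals[1, , drop = FALSE]
  for (i in seq_len(nrow(ivals))[-1]) {
    k <- nrow(merged)
    if (ivals[i, 1] <= merged[k, 2]) merged[k, 2] <- max(merged[k, 2], ivals[i, 2])
    else merged <- rbind(merged, ivals[i, ])
  }
  merged
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2) return(0)
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                    poly[-nrow(poly), , drop = FALSE])^2)))
}

# Clip one polyline against the union of disks. Returns a list of pieces:
# poly matrix plus start_cut / end_cut flags (TRUE when the piece boundary
# is a disk crossing rather than an original terminal).
clip_polyline_outside_disks <- function(poly, cx, cy, r) {
  eps <- 1e-9
  pieces <- list()
  cur <- NULL; cur_start_cut <- FALSE
  close_cur <- function(end_cut) {
    if (!is.null(cur) && nrow(cur) >= 2 && polyline_length(cur) > 1e-9)
      pieces[[length(pieces) + 1L]] <<-
        list(poly = cur, start_cut = cur_start_cut, end_cut = end_cut)
    cur <<- NULL
  }
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    inside <- segment_inside_intervals(a, b, cx, cy, r)
    # complement of `inside` within [0, 1]
    kept <- NULL; t <- 0
    if (!is.null(inside)) {
      for (k in seq_len(nrow(inside))) {
        if (inside[k, 1] > t + eps) kept <- rbind(kept, c(t, inside[k, 1]))
        t <- max(t, inside[k, 2])
      }
    }
    if (t < 1 - eps) kept <- rbind(kept, c(t, 1))
    if (is.null(kept)) { close_cur(TRUE); next }
    for (k in seq_len(nrow(kept))) {
      t0 <- kept[k, 1]; t1 <- kept[k, 2]
      p0 <- a + t0 * (b - a); p1 <- a + t1 * (b - a)
      if (t0 <= eps && !is.null(cur)) {
        cur <- rbind(cur, p1)                 # continues the open piece
      } else {
        close_cur(TRUE)
        cur <- rbind(p0, p1)
        cur_start_cut <- !(i == 1 && t0 <= eps)
      }
      if (t1 < 1 - eps) close_cur(TRUE)
    }
  }
  close_cur(FALSE)
  pieces
}

# proper intersection of segments p1->p2 and q1->q2, excluding endpoints;
# returns c(t, u) or NULL
segment_intersection <- function(p1, p2, q1, q2, eps = 1e-9) {
  d1 <- p2 - p1; d2 <- q2 - q1
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(NULL)     # parallel / collinear: ignore
  w <- q1 - p1
  t <- (w[1] * d2[2] - w[2] * d2[1]) / denom
  u <- (w[1] * d1[2] - w[2] * d1[1]) / denom
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  c(t, u)
}

# Build the apparent planar network from the grown forest.
# Nodes: surviving original terminals (soma-root / junction / endpoint),
# disk-cut points (endpoint, or soma-root when they relocate the root of a
# root edge), and crossing points (junction). Edges: polyline pieces split
# at crossings. Junction count = nodes of degree >= 3; endpoint count =
# degree-1 nodes excluding soma roots.
apparent_network <- function(nodes, edges, cells, clip_margin_um) {
  cx <- cells$x; cy <- cells$y
  r <- cells$r + clip_margin_um
  node_x <- numeric(0); node_y <- numeric(0); node_kind <- character(0)
  orig_map <- integer(max(0L, max(c(0L, nodes$id))))   # orig id -> new id
  new_node <- function(x, y, kind) {
    node_x[length(node_x) + 1L] <<- x
    node_y[length(node_y) + 1L] <<- y
    node_kind[length(node_kind) + 1L] <<- kind
    length(node_x)
  }
  get_orig <- function(id) {
    if (orig_map[id] == 0L)
      orig_map[id] <<- new_node(nodes$x[id], nodes$y[id], nodes$kind[id])
    orig_map[id]
  }
  # 1) clip every edge against the grown soma disks
  pieces <- list()
  for (e in edges) {
    cl <- clip_polyline_outside_disks(e$poly, cx, cy, r)
    for (pidx in seq_along(cl)) {
      pc <- cl[[pidx]]
      # a cut at the proximal end of a root edge relocates the soma root to
      # the disk exit point; any later cut is a plain endpoint
      from <- if (pc$start_cut) {
        kind <- if (pidx == 1L && nodes$kind[e$from] == "soma-root")
          "soma-root" else "endpoint"
        new_node(pc$poly[1, 1], pc$poly[1, 2], kind)
      } else get_orig(e$from)
      to <- if (pc$end_cut)
        new_node(pc$poly[nrow(pc$poly), 1], pc$poly[nrow(pc$poly), 2],
                 "endpoint")
      else get_orig(e$to)
      pieces[[length(pieces) + 1L]] <-
        list(from = from, to = to, poly = pc$poly)
    }
  }
  # 2) find crossings between segments of different pieces
  if (length(pieces) > 1) {
    segtab <- do.call(rbind, lapply(seq_along(pieces), function(pi) {
      pl <- pieces[[pi]]$poly
      n <- nrow(pl) - 1
      cbind(pi, seq_len(n), pl[seq_len(n), 1], pl[seq_len(n), 2],
            pl[seq_len(n) + 1, 1], pl[seq_len(n) + 1, 2])
    }))
    cross <- vector("list", length(pieces))   # per piece: (seg, t, node)
    ns <- nrow(segtab)
    # coarse bounding-box prefilter
    xmin <- pmin(segtab[, 3], segtab[, 5]); xmax <- pmax(segtab[, 3], segtab[, 5])
    ymin <- pmin(segtab[, 4], segtab[, 6]); ymax <- pmax(segtab[, 4], segtab[, 6])
    ord <- order(xmin)
    for (ii in seq_len(ns - 1)) {
      i <- ord[ii]
      for (jj in (ii + 1):ns) {
        j <- ord[jj]
        if (xmin[j] > xmax[i]) break
        if (segtab[i, 1] == segtab[j, 1]) next   # same piece
        if (ymin[j] > ymax[i] || ymax[j] < ymin[i]) next
        hit <- segment_intersection(segtab[i, 3:4], segtab[i, 5:6],
                                    segtab[j, 3:4], segtab[j, 5:6])
        if (is.null(hit)) next
        pt <- segtab[i, 3:4] + hit[1] * (segtab[i, 5:6] - segtab[i, 3:4])
        nd <- new_node(pt[1], pt[2], "junction")
        pi_ <- segtab[i, 1]; pj <- segtab[j, 1]
        cross[[pi_]] <- rbind(cross[[pi_]], c(segtab[i, 2], hit[1], nd))
        cross[[pj]] <- rbind(cross[[pj]], c(segtab[j, 2], hit[2], nd))
      }
    }
    # 3) split pieces at their crossing points
    out <- list()
    for (pi in seq_along(pieces)) {
      pc <- pieces[[pi]]
      cr <- cross[[pi]]
      if (is.null(cr)) { out[[length(out) + 1L]] <- pc; next }
      cr <- cr[order(cr[, 1], cr[, 2]), , drop = FALSE]
      cur <- pc$poly[1, , drop = FALSE]
      from <- pc$from
      ci <- 1L
      for (s in seq_len(nrow(pc$poly) - 1)) {
        a <- pc$poly[s, ]; b <- pc$poly[s + 1, ]
        while (ci <= nrow(cr) && cr[ci, 1] == s) {
          pt <- a + cr[ci, 2] * (b - a)
          cur <- rbind(cur, pt)
          out[[length(out) + 1L]] <-
            list(from = from, to = cr[ci, 3], poly = cur)
          cur <- matrix(pt, ncol = 2)
          from <- cr[ci, 3]
          ci <- ci + 1L
        }
        cur <- rbind(cur, b)
      }
      out[[length(out) + 1L]] <- list(from = from, to = pc$to, poly = cur)
    }
    pieces <- out
  }
  list(nodes = data.frame(id = seq_along(node_x), x = node_x, y = node_y,
                          kind = node_kind, stringsAsFactors = FALSE),
       edges = pieces)
}

# metrics of the apparent network; `nodes`/`edges` as returned above
true_metrics_from_graph <- function(net, cells) {
  deg <- integer(nrow(net$nodes))
  total <- 0
  for (e in net$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
    total <- total + polyline_length(e$poly)
  }
  nb <- length(net$edges)
  data.frame(n_somata = nrow(cells),
             n_branches = nb,
             n_junctions = sum(deg >= 3L),
             n_endpoints = sum(deg == 1L & net$nodes$kind != "soma-root"),
             total_branch_length_um = total,
             avg_branch_length_um = if (nb > 0) total / nb else 0)
}

# --- rendering ------------------------------------------------------------

# stamp an anti-aliased disk into img (ADU peak `value`), max-composited
stamp_disk <- function(img, cx, cy, r_um, ps, value) {
  nr <- nrow(img); nc <- ncol(img)
  r_px <- r_um / ps
  c0 <- max(1L, floor(cx / ps - r_px - 1)); c1 <- min(nc, ceiling(cx / ps + r_px + 2))
  r0 <- max(1L, floor(cy / ps - r_px - 1)); r1 <- min(nr, ceiling(cy / ps + r_px + 2))
  if (c0 > c1 || r0 > r1) return(img)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix((cols - 0.5) * ps, length(rows), length(cols), byrow = TRUE)
  Y <- matrix((rows - 0.5) * ps, length(rows), length(cols))
  d_px <- sqrt((X - cx)^2 + (Y - cy)^2) / ps
  cov <- pmin(pmax(r_px + 0.5 - d_px, 0), 1)
  img[rows, cols] <- pmax(img[rows, cols], value * cov)
  img
}

# stamp an anti-aliased thick segment (centerline a->b, half-width in px)
stamp_segment <- function(img, a, b, ps, half_w_px, value) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- half_w_px + 1.5
  c0 <- max(1L, floor(min(a[1], b[1]) / ps - pad))
  c1 <- min(nc, ceiling(max(a[1], b[1]) / ps + pad))
  r0 <- max(1L, floor(min(a[2], b[2]) / ps - pad))
  r1 <- min(nr, ceiling(max(a[2], b[2]) / ps + pad))
  if (c0 > c1 || r0 > r1) return(img)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix((cols - 0.5) * ps, length(rows), length(cols), byrow = TRUE)
  Y <- matrix((rows - 0.5) * ps, length(rows), length(cols))
  d <- b - a; L2 <- sum(d^2)
  if (L2 == 0) return(img)
  tt <- pmin(pmax(((X - a[1]) * d[1] + (Y - a[2]) * d[2]) / L2, 0), 1)
  d_px <- sqrt((X - (a[1] + tt * d[1]))^2 + (Y - (a[2] + tt * d[2]))^2) / ps
  cov <- pmin(pmax(half_w_px + 0.5 - d_px, 0), 1)
  img[rows, cols] <- pmax(img[rows, cols], value * cov)
  img
}

render_channels <- function(p, cells, edges, n_px) {
  ps <- p$pixel_size_um
  dapi <- matrix(0, n_px, n_px)
  map2 <- matrix(0, n_px, n_px)
  for (ci in seq_len(nrow(cells))) {
    dapi <- stamp_disk(dapi, cells$x[ci], cells$y[ci], cells$r[ci], ps,
                       0.9 * p$signal_level)
    map2 <- stamp_disk(map2, cells$x[ci], cells$y[ci], cells$r[ci], ps,
                       p$soma_brightness * p$signal_level)
  }
  for (e in edges) {
    arc <- e$arc0_um
    for (i in seq_len(nrow(e$poly) - 1)) {
      a <- e$poly[i, ]; b <- e$poly[i + 1, ]
      seg_len <- sqrt(sum((b - a)^2))
      fall <- exp(-(arc + seg_len / 2) / p$falloff_length_um)
      map2 <- stamp_segment(map2, a, b, ps, e$width_px / 2,
                            p$signal_level * fall)
      arc <- arc + seg_len
    }
  }
  if (p$psf_sigma_um > 0) {
    k <- gaussian_kernel_1d(p$psf_sigma_um / ps)
    dapi <- .sep_convolve(dapi, k, k)
    map2 <- .sep_convolve(map2, k, k)
  }
  list(dapi = dapi + p$background_level, map2 = map2 + p$background_level)
}

apply_noise <- function(img, p) {
  if (p$noise_model == "none") return(img)
  n <- length(img)
  if (p$noise_model == "poisson") {
    lam <- pmax(img * p$photons_per_adu, 0)
    img[] <- stats::rpois(n, lam) / p$photons_per_adu
  }
  img + stats::rnorm(n, 0, p$noise_sd)
}

quantize <- function(img, bit_depth) {
  mx <- 2^bit_depth - 1
  round(pmin(pmax(img, 0), mx))
}

# --- public generator -----------------------------------------------------

#' Generate one synthetic two-channel acquisition with ground truth
#'
#' Deterministic for a fixed `params$seed`: places non-overlapping nuclei,
#' grows the neurite forest, renders anti-aliased DAPI and marker channels,
#' applies the configured noise model last, and returns the true graph with
#' analytically computed morphometry (branch lengths measured outside the
#' nucleus disks, where the measurement pipeline can see them).
#'
#' @param params A [generator_params()] list.
#' @return A list with elements `acquisition` (fields `dapi`, `map2`,
#'   `pixel_size_um`, `provenance`) and `truth` (fields `cell_centers`,
#'   `nodes`, `edges`, `true_metrics`).
#' @export
generate_acquisition <- function(params) {
  validate_generator_params(params)
  set.seed(params$seed)
  n_px <- field_pixels(params)
  if (n_px < 4L) stop("field too small for the given pixel size")
  field_um <- n_px * params$pixel_size_um
  cells <- place_cells(params, field_um)
  forest <- grow_forest(params, cells, field_um)
  nodes <- reclassify_nodes(forest$nodes, forest$edges)
  chans <- render_channels(params, cells, forest$edges, n_px)
  dapi <- quantize(apply_noise(chans$dapi, params), params$bit_depth)
  map2 <- quantize(apply_noise(chans$map2, params), params$bit_depth)
  acq <- structure(list(dapi = image2d(dapi, params$pixel_size_um,
                                       params$bit_depth),
                        map2 = image2d(map2, params$pixel_size_um,
                                       params$bit_depth),
                        pixel_size_um = params$pixel_size_um,
                        provenance = params),
                   class = "acquisition")
  net <- apparent_network(nodes, forest$edges, cells,
                          params$soma_clip_margin_um)
  truth <- list(cell_centers = cells,
                nodes = net$nodes,
                edges = net$edges,
                tree_nodes = nodes,
                tree_edges = forest$edges,
                true_metrics = true_metrics_from_graph(net, cells))
  list(acquisition = acq, truth = truth)
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf("acquisition: %d x %d px at %.4g um/px (dapi + map2)\n",
              nrow(x$dapi), ncol(x$dapi), x$pixel_size_um))
  invisible(x)
}

#' Generate a two-group cohort of synthetic acquisitions
#'
#' Builds `n_images_per_group * n_replicates` acquisitions per group.
#' Per-image seeds are drawn reproducibly from `master_seed`, so the whole
#' cohort is a deterministic function of the master seed and the two
#' parameter sets. A KO-like group is usually emulated by lowering
#' `branching_prob` (and/or `neurites_per_cell_range`) in `params_ko` while
#' keeping `n_cells` fixed, which preserves equal somata across groups.
#'
#' @param params_wt,params_ko [generator_params()] for the two groups.
#' @param n_images_per_group Acquisitions per replicate per group (>= 1).
#' @param n_replicates Biological replicates per group.
#' @param master_seed Master seed for the per-image seed stream.
#' @return A list of class `cohort`; each element has `acquisition`,
#'   `truth`, `group` (`"WT"` / `"KO"`), `replicate` and `image_id`.
#' @export
generate_group <- function(params_wt, params_ko, n_images_per_group,
                           n_replicates = 3L, master_seed = params_wt$seed) {
  if (n_images_per_group < 1L) stop("n_images_per_group must be >= 1")
  plan <- cohort_plan(n_images_per_group, n_replicates, master_seed)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- if (plan$group[i] == "WT") params_wt else params_ko
    p$seed <- plan$seed[i]
    g <- generate_acquisition(p)
    out[[i]] <- list(acquisition = g$acquisition, truth = g$truth,
                     group = plan$group[i], replicate = plan$replicate[i],
                     image_id = plan$image_id[i])
  }
  structure(out, class = "cohort")
}

# deterministic per-image seed/label table shared by generate_group and the
# streaming experiment driver
cohort_plan <- function(n_images_per_group, n_replicates, master_seed) {
  set.seed(master_seed)
  n_tot <- 2L * n_images_per_group * n_replicates
  seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  grid <- expand.grid(image = seq_len(n_images_per_group),
                      replicate = seq_len(n_replicates),
                      group = c("WT", "KO"),
                      stringsAsFactors = FALSE)
  grid$seed <- seeds
  grid$image_id <- sprintf("%s_rep%d_img%02d", grid$group, grid$replicate,
                           grid$image)
  grid
}
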