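#' Parameters of a synthetic dissociated retinal culture
#'
#' Defaults emulate the study conditions: seeding density 9.3e3 cells/mm^2,
#' culture ages of 3, 7 or 17 days in vitro (DIV), neuron migration speeds
#' of 10-20 um/h on the smooth gap surface, strong neuron adhesion to the
#' textured branch surface, and glial growth concentrated in gap regions
#' close to branches. The neuron:glia ratio of the dissociated retina is
#' not prescribed by the culture protocol; 0.7 is used as a configurable
#' default since only the spatial contrast between the two populations is
#' under test.
#'
#' @param seed_density cells per mm^2.
#' @param neuron_fraction fraction of seeded cells that are neurons (0-1).
#' @param div culture age at imaging, days in vitro.
#' @param migration_speed range (um/h) of neuron migration speeds on the gap.
#' @param migration_hours upper bound (hours) on active migration.
#' @param settle_hours mean of the exponentially distributed time after
#'   which a migrating neuron settles (neuron-neuron aggregation starts to
#'   dominate over substrate exploration).
#' @param cnt_neuron_affinity probability that a neuron stepping onto the
#'   branch surface attaches permanently.
#' @param gap_glia_affinity distance scale (um) of glial growth decline away
#'   from branches; glia in low-proximity gap regions rarely spread
#'   (the "desert" regions).
#' @param glia_cnt_prob probability that an individual glial cell sits on the
#'   branch surface rather than in a gap.
#' @param cluster_scale spatial scale (um) over which gap neurons aggregate
#'   into soma clusters.
#' @param process_length_mean mean single-process length (um) at maturity.
#' @param glia_radius range (um) of base glial coverage disk radii.
#' @param glia_coverage_scale global multiplier on glial coverage radii;
#'   0 disables glial coverage entirely.
#' @param bundle_k number of neighbouring clusters each soma cluster sends
#'   process bundles to.
#' @param boundary_reach distance (um) within which a gap cluster connects to
#'   the nearest branch edge (the "boundary" region behaviour).
#' @param rng_seed integer seed; all stochasticity flows from it.
#' @return list of class `culture_params`.
#' @export
culture_params <- function(seed_density = 9.3e3, neuron_fraction = 0.7,
                           div = 17, migration_speed = c(10, 20),
                           migration_hours = 96,
                           settle_hours = 24,
                           cnt_neuron_affinity = 0.9,
                           gap_glia_affinity = 120,
                           glia_cnt_prob = 0.02,
                           cluster_scale = 200,
                           process_length_mean = 140,
                           glia_radius = c(7, 14),
                           glia_coverage_scale = 1,
                           bundle_k = 2,
                           boundary_reach = 150,
                           rng_seed = 1L) {
  stopifnot(seed_density >= 0, neuron_fraction > 0, neuron_fraction < 1,
            all(migration_speed > 0), div > 0)
  structure(as.list(environment()), class = "culture_params")
}

#' Seed cells onto an electrode mask
#'
#' Homogeneous spatial Poisson seeding at `seed_density` over the bounding
#' rectangle; each cell is a neuron with probability `neuron_fraction`.
#'
#' @param mask a `raster_mask` (built with `keep_ids = TRUE` if processes
#'   are to be grown later).
#' @param params a [culture_params()].
#' @return object of class `synthetic_scene` with `somas`, empty
#'   `processes`/`glial_regions`, the field bounds and the seed.
#' @export
seed_cells <- function(mask, params) {
  stopifnot(inherits(mask, "raster_mask"), inherits(params, "culture_params"))
  b <- scene_bounds(mask)
  area_mm2 <- (b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"]) / 1e6
  if (area_mm2 <= 0) stop("zero-area mask", call. = FALSE)
  set.seed(params$rng_seed)
  n <- stats::rpois(1, params$seed_density * area_mm2)
  somas <- data.frame(
    x = stats::runif(n, b["xmin"], b["xmax"]),
    y = stats::runif(n, b["ymin"], b["ymax"]),
    kind = ifelse(stats::runif(n) < params$neuron_fraction, "neuron", "glia"),
    cluster = rep(NA_integer_, n))
  structure(
    list(somas = somas, processes = list(), glial_regions = NULL,
         bounds = b, mask_res = mask$res, mask = mask, params = params,
         rng_seed = params$rng_seed, div = 0, label = mask$label),
    class = "synthetic_scene")
}

scene_bounds <- function(mask) {
  c(xmin = unname(mask$origin["x"]),
    xmax = unname(mask$origin["x"]) + ncol(mask$cnt) * mask$res,
    ymin = unname(mask$origin["y"]),
    ymax = unname(mask$origin["y"]) + nrow(mask$cnt) * mask$res)
}

mask_label_at <- function(mask, x, y) {
  cx <- pmin(pmax(ceiling((x - mask$origin["x"]) / mask$res), 1L), ncol(mask$cnt))
  ry <- pmin(pmax(ceiling((y - mask$origin["y"]) / mask$res), 1L), nrow(mask$cnt))
  mask$cnt[cbind(ry, cx)]
}

mask_seg_at <- function(mask, x, y) {
  cx <- pmin(pmax(ceiling((x - mask$origin["x"]) / mask$res), 1L), ncol(mask$cnt))
  ry <- pmin(pmax(ceiling((y - mask$origin["y"]) / mask$res), 1L), nrow(mask$cnt))
  mask$seg[cbind(ry, cx)]
}

# total-length development curve: process complexity peaks at 7 DIV and is
# partly pruned/bundled away by 17 DIV
div_count_weight <- function(div) stats::approx(c(0, 3, 7, 17, 40),
                                                c(0, 0.5, 1, 0.55, 0.45),
                                                xout = div, rule = 2)$y
div_length_weight <- function(div) stats::approx(c(0, 3, 7, 17, 40),
                                                 c(0.2, 0.7, 1, 1.05, 1.05),
                                                 xout = div, rule = 2)$y
div_glia_growth <- function(div) sqrt(div / 7)

#' Evolve a seeded scene to a culture age
#'
#' Rule-based development in 1 h steps: (1) neurons in gaps take an
#' unbiased random walk at 10-20 um/h and attach permanently (with
#' probability `cnt_neuron_affinity`) when they step onto a branch;
#' (2) gap neurons aggregate into soma clusters on the `cluster_scale`;
#' (3) attached neurons grow processes that follow branch edges, turning at
#' branch junctions, while clusters grow straight process bundles to
#' neighbouring clusters and -- within `boundary_reach` of a branch -- to
#' the nearest branch edge; process count and length rise to a maximum
#' complexity near 7 DIV, after which bundling and pruning reduce the total;
#' (4) glial coverage grows as disks in the gaps with growth probability
#' decaying with distance from the branches, producing covered boundary and
#' cluster regions near branches and sparse deserts far from them; a small
#' fraction of glia sit on the branches.
#'
#' Edge-following processes are laid on distinct inset lines along each
#' branch edge, so that distinct processes of the default scene remain
#' resolvable; deliberate bundles are emitted as single polylines (the
#' overlap-insensitive measurement counts a bundle once, and so does the
#' ground truth).
#'
#' @param scene a seeded `synthetic_scene`.
#' @param mask the `raster_mask` it was seeded on (with `seg` ids for edge
#'   following).
#' @param tree the `segment_tree` behind the mask (for junction topology);
#'   optional for row patterns.
#' @param params optionally override the scene's [culture_params()].
#' @return the evolved `synthetic_scene`, including exact `ground_truth`
#'   herding measurements.
#' @export
simulate_development <- function(scene, mask, tree = NULL, params = scene$params) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(params$rng_seed + 1L)
  somas <- scene$somas
  b <- scene$bounds
  div <- params$div

  ## (1) migration ---------------------------------------------------------
  is_neu <- somas$kind == "neuron"
  x <- somas$x; y <- somas$y
  attached <- rep(FALSE, nrow(somas))
  attached[is_neu] <- mask_label_at(mask, x[is_neu], y[is_neu]) &
    stats::runif(sum(is_neu)) < params$cnt_neuron_affinity
  steps <- round(min(div * 24, params$migration_hours))
  moving <- which(is_neu & !attached)
  settle <- stats::rexp(length(moving), 1 / params$settle_hours)
  for (t in seq_len(steps)) {
    if (!length(moving)) break
    active <- settle >= t
    moving <- moving[active]
    settle <- settle[active]
    if (!length(moving)) break
    sp <- stats::runif(length(moving), params$migration_speed[1], params$migration_speed[2])
    th <- stats::runif(length(moving), 0, 2 * pi)
    x[moving] <- pmin(pmax(x[moving] + sp * cos(th), b["xmin"] + 1), b["xmax"] - 1)
    y[moving] <- pmin(pmax(y[moving] + sp * sin(th), b["ymin"] + 1), b["ymax"] - 1)
    on_cnt <- mask_label_at(mask, x[moving], y[moving])
    stick <- on_cnt & stats::runif(length(moving)) < params$cnt_neuron_affinity
    attached[moving[stick]] <- TRUE
    moving <- moving[!stick]
    settle <- settle[!stick]
  }
  somas$x <- x; somas$y <- y
  on_cnt_final <- mask_label_at(mask, somas$x, somas$y)

  ## (2) clustering of gap neurons -----------------------------------------
  gap_neu <- which(is_neu & !on_cnt_final)
  clusters <- NULL
  if (length(gap_neu) >= 3) {
    cs <- params$cluster_scale
    gx <- floor((somas$x[gap_neu] - b["xmin"]) / cs)
    gy <- floor((somas$y[gap_neu] - b["ymin"]) / cs)
    key <- gx * 1e6 + gy
    ids <- match(key, unique(key))
    cnts <- tabulate(ids)
    keep <- which(cnts >= 3)
    if (length(keep)) {
      cx <- tapply(somas$x[gap_neu], ids, mean)[keep]
      cy <- tapply(somas$y[gap_neu], ids, mean)[keep]
      # snap each centre to the member soma nearest the centroid: cluster
      # centres are somas, and somas sit in the gap (a raw centroid of a
      # grid cell straddling a branch could land on the branch)
      for (q in seq_along(keep)) {
        memb_q <- which(ids == keep[q])
        dq <- (somas$x[gap_neu[memb_q]] - cx[q])^2 +
          (somas$y[gap_neu[memb_q]] - cy[q])^2
        w <- memb_q[which.min(dq)]
        cx[q] <- somas$x[gap_neu[w]]; cy[q] <- somas$y[gap_neu[w]]
      }
      clusters <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                             n = cnts[keep], id = seq_along(keep))
      # soma blob radius adapts to the local gap clearance
      if (!is.null(tree)) {
        r <- tree$rects
        dd <- vapply(seq_len(nrow(clusters)), function(i) {
          dx <- pmax(0, pmax(r[, "x0"] - clusters$x[i], clusters$x[i] - r[, "x1"]))
          dy <- pmax(0, pmax(r[, "y0"] - clusters$y[i], clusters$y[i] - r[, "y1"]))
          min(sqrt(dx^2 + dy^2))
        }, 0)
        clusters$r <- pmax(6, pmin(18, dd - 3))
      } else clusters$r <- 18
      # aggregation pulls member somas toward the cluster centre
      shrink <- if (div >= 7) 0.3 else 0.7
      memb <- ids %in% keep
      cid <- match(ids[memb], keep)
      somas$cluster[gap_neu[memb]] <- cid
      somas$x[gap_neu[memb]] <- clusters$x[cid] +
        (somas$x[gap_neu[memb]] - clusters$x[cid]) * shrink
      somas$y[gap_neu[memb]] <- clusters$y[cid] +
        (somas$y[gap_neu[memb]] - clusters$y[cid]) * shrink
    }
  }

  ## (2b) branch neurons aggregate into small clusters along their branch
  somas$on_cnt <- mask_label_at(mask, somas$x, somas$y)
  branch_clusters <- NULL
  if (!is.null(mask$seg) && !is.null(tree)) {
    bn <- which(is_neu & somas$on_cnt)
    if (length(bn)) {
      sid <- mask_seg_at(mask, somas$x[bn], somas$y[bn])
      ok <- !is.na(sid) & sid > 0
      bn <- bn[ok]; sid <- sid[ok]
      if (length(bn)) {
        segdf <- tree$segments
        horiz <- segdf$orientation[sid] == "h"
        axis_pos <- ifelse(horiz, somas$x[bn], somas$y[bn])
        key <- paste0(sid, ":", floor(axis_pos / 120))
        cid <- match(key, unique(key))
        w0 <- segdf$width[1]
        r_bb <- edge_slot_geometry(w0, mask$res)$r_bb
        branch_clusters <- data.frame(
          x = as.numeric(tapply(ifelse(horiz, somas$x[bn], segdf$x0[sid]), cid, mean)),
          y = as.numeric(tapply(ifelse(horiz, segdf$y0[sid], somas$y[bn]), cid, mean)),
          r = r_bb)
      }
    }
  }

  ## (3) processes ----------------------------------------------------------
  processes <- list()
  cw <- div_count_weight(div)
  lw <- div_length_weight(div)
  if (!is.null(mask$seg)) {
    processes <- c(processes,
                   grow_branch_processes(somas, attached | (is_neu & on_cnt_final),
                                         mask, tree, params, cw, lw))
  }
  rsub <- NULL
  if (!is.null(tree)) {
    r <- tree$rects
    reachb <- params$boundary_reach
    keepr <- r[, "x1"] >= b[["xmin"]] - reachb & r[, "x0"] <= b[["xmax"]] + reachb &
      r[, "y1"] >= b[["ymin"]] - reachb & r[, "y0"] <= b[["ymax"]] + reachb
    rsub <- r[keepr, , drop = FALSE]
  }
  if (!is.null(clusters)) {
    processes <- c(processes,
                   grow_gap_bundles(clusters, mask, tree, params, cw, lw, b))
  }
  # boundary-region individuals: unclustered gap neurons near a branch grow
  # a single process to the closest branch edge
  if (!is.null(rsub) && nrow(rsub)) {
    cand <- which(is_neu & !somas$on_cnt & is.na(somas$cluster))
    if (length(cand) > 400) cand <- sort(sample(cand, 400))
    grow <- stats::runif(length(cand)) < min(1, cw + 0.3)
    for (qq in cand[grow]) {
      px <- somas$x[qq]; py <- somas$y[qq]
      dx <- pmax(0, pmax(rsub[, "x0"] - px, px - rsub[, "x1"]))
      dy <- pmax(0, pmax(rsub[, "y0"] - py, py - rsub[, "y1"]))
      dd <- sqrt(dx^2 + dy^2)
      k <- which.min(dd)
      if (dd[k] < 25 || dd[k] > params$boundary_reach) next
      tx <- min(max(px, rsub[k, "x0"]), rsub[k, "x1"])
      ty <- min(max(py, rsub[k, "y0"]), rsub[k, "y1"])
      processes[[length(processes) + 1L]] <- rbind(c(px, py), c(tx, ty))
    }
  }

  ## (4) glial coverage -----------------------------------------------------
  glia <- which(somas$kind == "glia")
  glial_regions <- NULL
  if (length(glia)) {
    gx <- somas$x[glia]; gy <- somas$y[glia]
    lab_g <- mask_label_at(mask, gx, gy)
    # glia attach to the branch surface only rarely; the rest of those that
    # landed on a branch relocate into the gaps
    on_cnt_g <- lab_g & stats::runif(length(glia)) < params$glia_cnt_prob
    fix <- which(lab_g & !on_cnt_g)
    reach <- 60
    for (try in 1:25) {
      if (!length(fix)) break
      # nudge to a random nearby gap location, widening the search if needed
      xx <- pmin(pmax(gx[fix] + stats::runif(length(fix), -reach, reach),
                      b["xmin"] + 1), b["xmax"] - 1)
      yy <- pmin(pmax(gy[fix] + stats::runif(length(fix), -reach, reach),
                      b["ymin"] + 1), b["ymax"] - 1)
      ok <- !mask_label_at(mask, xx, yy)
      gx[fix[ok]] <- xx[ok]; gy[fix[ok]] <- yy[ok]
      fix <- fix[!ok]
      if (try %% 5 == 0) reach <- reach * 1.5
    }
    somas$x[glia] <- gx; somas$y[glia] <- gy
    # growth prob decays with distance to the nearest branch (deserts)
    dmap <- EBImage::imageData(EBImage::distmap(1 - mask$cnt * 1L)) * mask$res
    cxi <- pmin(pmax(ceiling((gx - mask$origin["x"]) / mask$res), 1L), ncol(mask$cnt))
    ryi <- pmin(pmax(ceiling((gy - mask$origin["y"]) / mask$res), 1L), nrow(mask$cnt))
    dist_g <- dmap[cbind(ryi, cxi)]
    grow_p <- exp(-dist_g / params$gap_glia_affinity)
    grow_p[on_cnt_g] <- 0.5   # branch glia spread little but exist
    grows <- stats::runif(length(glia)) < grow_p
    r <- stats::runif(length(glia), params$glia_radius[1], params$glia_radius[2]) *
      div_glia_growth(div)
    r[!grows] <- 8   # individual non-spreading glia (single-cell footprint)
    r <- r * params$glia_coverage_scale
    glial_regions <- data.frame(x = gx, y = gy, r = r, on_cnt = on_cnt_g)
  }

  # every process vertex must lie inside the field: truncate at the first
  # boundary crossing (the field of view simply ends there)
  processes <- Filter(Negate(is.null),
                      lapply(processes, clip_polyline, b = b, eps = 1))

  scene$somas <- somas
  scene$clusters <- clusters
  scene$branch_clusters <- branch_clusters
  scene$processes <- processes
  scene$glial_regions <- glial_regions
  scene$div <- div
  scene$params <- params
  scene$ground_truth <- NULL
  scene$ground_truth <- ground_truth_measurements(scene, mask)
  scene
}

# edge-line slots and centreline soma-blob radius for a branch of width w:
# processes occupy inset lines from just inside the edge down to a clearance
# around the centreline soma clusters; wide branches host more lines
edge_slot_geometry <- function(w, res) {
  inset_min <- 1.8 * res
  if (w >= 60) {
    r_bb <- 10
    inset_max <- w / 2 - (r_bb + 4.5)
  } else {
    inset_max <- max(inset_min, min(8, w / 2 - 5.5))
    r_bb <- min(10, max(1.5, w / 2 - inset_max - 4.5))
  }
  n_slots <- max(1L, min(6L, floor((inset_max - inset_min) / (3 * res)) + 1L))
  insets <- if (n_slots == 1) (inset_min + inset_max) / 2 else
    seq(inset_min, inset_max, length.out = n_slots)
  list(insets = insets, n_slots = n_slots, r_bb = r_bb)
}

# processes following branch edges, turning at junctions; one process per
# free (segment, side, inset-slot) so that default scenes stay resolvable
grow_branch_processes <- function(somas, eligible, mask, tree, params, cw, lw) {
  idx <- which(eligible)
  if (!length(idx)) return(list())
  seg <- if (!is.null(tree)) tree$segments else NULL
  w <- if (!is.null(seg)) seg$width[1] else NA
  res <- mask$res
  children <- NULL
  if (!is.null(seg) && any(!is.na(seg$parent))) {
    children <- split(seq_len(nrow(seg)), factor(seg$parent, levels = seq_len(nrow(seg))))
  }
  sg <- edge_slot_geometry(w, res)
  insets <- sg$insets
  n_slots <- sg$n_slots
  slots <- new.env(parent = emptyenv())
  take_slot <- function(k, s) {
    key <- paste0(k, ":", s)
    used <- get0(key, envir = slots, ifnotfound = 0L)
    if (used >= n_slots) return(NA_real_)
    assign(key, used + 1L, envir = slots)
    insets[used + 1L]
  }
  out <- vector("list", length(idx))
  nproc <- 0L
  sid_all <- mask_seg_at(mask, somas$x[idx], somas$y[idx])
  for (q in seq_along(idx)) {
    i <- idx[q]
    k <- sid_all[q]
    if (is.na(k) || k == 0L) next
    n_p <- 1L + stats::rbinom(1L, 1L, min(1, cw))
    for (pp in seq_len(n_p)) {
      len <- params$process_length_mean * lw * stats::rexp(1) + 20
      poly <- walk_edges(k, somas$x[i], somas$y[i], len, seg, children,
                         take_slot, w)
      if (!is.null(poly)) {
        nproc <- nproc + 1L
        out[[nproc]] <- poly
      }
    }
  }
  out[seq_len(nproc)]
}

walk_edges <- function(k, sx, sy, len, seg, children, take_slot, w) {
  side <- sample(c(1, -1), 1)
  inset <- take_slot(k, side)
  if (is.na(inset)) {
    side <- -side
    inset <- take_slot(k, side)
    if (is.na(inset)) return(NULL)
  }
  pts <- matrix(NA_real_, nrow = 40, ncol = 2)
  np <- 0L
  last_x <- NA_real_; last_y <- NA_real_
  add <- function(x, y) {
    np <<- np + 1L
    if (np > nrow(pts)) pts <<- rbind(pts, matrix(NA_real_, 40, 2))
    pts[np, ] <<- c(x, y)
    last_x <<- x; last_y <<- y
  }
  horiz <- seg$orientation[k] == "h"
  off <- side * (w / 2 - inset)
  rowlike <- is.null(children)   # row patterns: pick a random direction
  if (horiz) {
    dirn <- if (rowlike) sample(c(1, -1), 1) else sign(seg$x1[k] - seg$x0[k])
    if (dirn == 0) dirn <- sample(c(1, -1), 1)
    cur <- min(max(sx, min(seg$x0[k], seg$x1[k])), max(seg$x0[k], seg$x1[k]))
    add(cur, seg$y0[k] + off)
  } else {
    dirn <- if (rowlike) sample(c(1, -1), 1) else sign(seg$y1[k] - seg$y0[k])
    if (dirn == 0) dirn <- sample(c(1, -1), 1)
    cur <- min(max(sy, min(seg$y0[k], seg$y1[k])), max(seg$y0[k], seg$y1[k]))
    add(seg$x0[k] + off, cur)
  }
  remaining <- len
  for (hop in 1:30) {
    tip <- if (horiz) {
      if (dirn > 0) max(seg$x0[k], seg$x1[k]) else min(seg$x0[k], seg$x1[k])
    } else {
      if (dirn > 0) max(seg$y0[k], seg$y1[k]) else min(seg$y0[k], seg$y1[k])
    }
    to_tip <- (tip - cur) * dirn
    if (to_tip < 0) to_tip <- 0
    kids <- if (!is.null(children)) children[[k]] else NULL
    if (remaining <= to_tip || is.null(kids) || !length(kids)) {
      endp <- cur + dirn * min(remaining, to_tip)
      if (horiz) add(endp, last_y) else add(last_x, endp)
      break
    }
    # turn onto the child on the same side as the followed edge, so the
    # corner stays on the branch surface
    kdir <- if (horiz) sign(seg$y1[kids] - seg$y0[kids])
            else sign(seg$x1[kids] - seg$x0[kids])
    same <- kids[kdir == sign(off)]
    kid <- if (length(same)) same[1] else kids[1]
    side2 <- sample(c(1, -1), 1)
    inset2 <- take_slot(kid, side2)
    if (is.na(inset2)) {
      side2 <- -side2
      inset2 <- take_slot(kid, side2)
    }
    if (is.na(inset2)) {  # no room: stop at the tip
      if (horiz) add(tip, last_y) else add(last_x, tip)
      break
    }
    off2 <- side2 * (w / 2 - inset2)
    if (horiz) {
      corner_x <- seg$x0[kid] + off2
      add(corner_x, last_y)
      remaining <- remaining - abs(corner_x - cur)
      k <- kid; horiz <- FALSE; off <- off2
      dirn <- sign(seg$y1[k] - seg$y0[k])
      cur <- last_y
    } else {
      corner_y <- seg$y0[kid] + off2
      add(last_x, corner_y)
      remaining <- remaining - abs(corner_y - cur)
      k <- kid; horiz <- TRUE; off <- off2
      dirn <- sign(seg$x1[k] - seg$x0[k])
      cur <- last_x
    }
    if (remaining <= 0) break
  }
  if (np < 2) return(NULL)
  pts[seq_len(np), , drop = FALSE]
}

# route a straight gap connection through intervening branches: processes
# cross a branch roughly perpendicular to its edge (climbing the sidewalls),
# never tangentially
route_through_branches <- function(p0, p1, rects, max_hops = 20) {
  pts <- matrix(p0, ncol = 2)
  cur <- p0
  for (it in seq_len(max_hops)) {
    d <- p1 - cur
    if (all(d == 0)) break
    # earliest rectangle entered strictly after the start
    with_x <- if (d[1] != 0) (c(rects[, "x0"], rects[, "x1"]) - cur[1]) / d[1] else NULL
    tx0 <- if (d[1] != 0) pmin(with_x[seq_len(nrow(rects))], with_x[-seq_len(nrow(rects))]) else rep(-Inf, nrow(rects))
    tx1 <- if (d[1] != 0) pmax(with_x[seq_len(nrow(rects))], with_x[-seq_len(nrow(rects))]) else rep(Inf, nrow(rects))
    if (d[1] == 0) {
      inx <- cur[1] >= rects[, "x0"] & cur[1] <= rects[, "x1"]
      tx0[!inx] <- Inf; tx1[!inx] <- -Inf
    }
    with_y <- if (d[2] != 0) (c(rects[, "y0"], rects[, "y1"]) - cur[2]) / d[2] else NULL
    ty0 <- if (d[2] != 0) pmin(with_y[seq_len(nrow(rects))], with_y[-seq_len(nrow(rects))]) else rep(-Inf, nrow(rects))
    ty1 <- if (d[2] != 0) pmax(with_y[seq_len(nrow(rects))], with_y[-seq_len(nrow(rects))]) else rep(Inf, nrow(rects))
    if (d[2] == 0) {
      iny <- cur[2] >= rects[, "y0"] & cur[2] <= rects[, "y1"]
      ty0[!iny] <- Inf; ty1[!iny] <- -Inf
    }
    t0 <- pmax(tx0, ty0); t1 <- pmin(tx1, ty1)
    hit <- which(t0 < t1 & t1 > 1e-9 & t0 < 1)
    if (!length(hit)) {
      pts <- rbind(pts, p1)
      break
    }
    k <- hit[which.min(t0[hit])]
    te <- max(t0[k], 0)
    E <- cur + te * d
    if (t1[k] >= 1) {           # destination inside this branch: enter and stop
      pts <- rbind(pts, E, p1)
      break
    }
    # cross perpendicular to the face that was entered
    if (tx0[k] >= ty0[k]) {   # entered through an x-face: cross in x
      xfar <- if (d[1] > 0) rects[k, "x1"] else rects[k, "x0"]
      X <- c(xfar + sign(d[1]) * 0.5, E[2])
    } else {                  # entered through a y-face: cross in y
      yfar <- if (d[2] > 0) rects[k, "y1"] else rects[k, "y0"]
      X <- c(E[1], yfar + sign(d[2]) * 0.5)
    }
    pts <- rbind(pts, E, X)
    cur <- X
  }
  pts
}

# truncate a polyline at its first exit from the field rectangle
clip_polyline <- function(pts, b, eps = 1) {
  xlo <- b[["xmin"]] + eps; xhi <- b[["xmax"]] - eps
  ylo <- b[["ymin"]] + eps; yhi <- b[["ymax"]] - eps
  inside <- pts[, 1] >= xlo & pts[, 1] <= xhi & pts[, 2] >= ylo & pts[, 2] <= yhi
  if (all(inside)) return(pts)
  if (!inside[1]) return(NULL)
  k <- which(!inside)[1]
  p0 <- pts[k - 1, ]; p1 <- pts[k, ]
  d <- p1 - p0
  t <- 1
  if (d[1] != 0) {
    t <- min(t, if (d[1] > 0) (xhi - p0[1]) / d[1] else (xlo - p0[1]) / d[1])
  }
  if (d[2] != 0) {
    t <- min(t, if (d[2] > 0) (yhi - p0[2]) / d[2] else (ylo - p0[2]) / d[2])
  }
  t <- max(t, 0)
  out <- rbind(pts[seq_len(k - 1), , drop = FALSE], p0 + t * d)
  if (nrow(out) < 2) return(NULL)
  out
}

# straight (lightly jittered) bundles between neighbouring soma clusters and
# from near-branch clusters to the closest branch edge
grow_gap_bundles <- function(clusters, mask, tree, params, cw, lw, b) {
  n <- nrow(clusters)
  out <- list()
  crv <- if ("r" %in% names(clusters)) clusters$r else rep(18, n)
  # links fan out: departure/arrival points on a cluster's rim keep at least
  # ~25 degrees between them so converging bundles stay resolvable
  used_ang <- vector("list", n)
  rim_point <- function(i, ang) {
    if (length(used_ang[[i]])) {
      for (try in 0:13) {
        cand <- ang + ((-1)^try) * ceiling(try / 2) * 25 * pi / 180
        if (all(abs(((cand - used_ang[[i]] + pi) %% (2 * pi)) - pi) >
                  24 * pi / 180)) { ang <- cand; break }
      }
    }
    used_ang[[i]] <<- c(used_ang[[i]], ang)
    c(clusters$x[i], clusters$y[i]) + (crv[i] + 4) * c(cos(ang), sin(ang))
  }
  if (n >= 2) {
    dmat <- as.matrix(stats::dist(clusters[, c("x", "y")]))
    diag(dmat) <- Inf
    pairs <- NULL
    for (i in seq_len(n)) {
      ord <- order(dmat[i, ])[seq_len(min(params$bundle_k, n - 1))]
      pairs <- rbind(pairs, cbind(pmin(i, ord), pmax(i, ord)))
    }
    pairs <- unique(pairs)
    n_links <- 1L + stats::rbinom(nrow(pairs), 2L, max(0, cw - 0.5))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      v <- c(clusters$x[j] - clusters$x[i], clusters$y[j] - clusters$y[i])
      L <- sqrt(sum(v^2))
      if (L < crv[i] + crv[j] + 15) next
      u <- v / L
      nv <- c(-u[2], u[1])
      # networks connect through intermediate clusters: skip the link if
      # another cluster sits on the path (keeps distinct bundles resolvable)
      other <- setdiff(seq_len(n), c(i, j))
      if (length(other)) {
        wx <- clusters$x[other] - clusters$x[i]
        wy <- clusters$y[other] - clusters$y[i]
        tproj <- (wx * u[1] + wy * u[2]) / L
        dperp <- abs(wx * nv[1] + wy * nv[2])
        if (any(tproj > 0.05 & tproj < 0.95 & dperp < crv[other] + 18)) next
      }
      offs <- (seq_len(n_links[p]) - (n_links[p] + 1) / 2) * 12
      for (o in offs) {
        a <- rim_point(i, atan2(u[2], u[1])) + nv * o
        z <- rim_point(j, atan2(-u[2], -u[1])) + nv * o
        poly <- if (!is.null(tree)) route_through_branches(a, z, tree$rects)
                else rbind(a, (a + z) / 2 + nv * stats::runif(1, -6, 6), z)
        if (nrow(poly) == 2) {   # free path: keep a little curvature
          poly <- rbind(a, (a + z) / 2 + nv * stats::runif(1, -6, 6), z)
        }
        out[[length(out) + 1L]] <- poly
      }
    }
  }
  # boundary connections to the nearest branch rectangle
  if (!is.null(tree)) {
    r <- tree$rects
    for (i in seq_len(n)) {
      px <- clusters$x[i]; py <- clusters$y[i]
      dx <- pmax(0, pmax(r[, "x0"] - px, px - r[, "x1"]))
      dy <- pmax(0, pmax(r[, "y0"] - py, py - r[, "y1"]))
      d <- sqrt(dx^2 + dy^2)
      k <- which.min(d)
      if (d[k] > params$boundary_reach || d[k] < crv[i] + 4) next
      tx <- min(max(px, r[k, "x0"]), r[k, "x1"])
      ty <- min(max(py, r[k, "y0"]), r[k, "y1"])
      u <- c(tx - px, ty - py) / d[k]
      a <- rim_point(i, atan2(u[2], u[1]))
      out[[length(out) + 1L]] <- rbind(a, c(tx, ty))
    }
  }
  out
}

#' Exact ground-truth herding measurements of a synthetic scene
#'
#' Process polyline lengths are split exactly by surface label (each segment
#' is cut at every pixel boundary of the mask); glial coverage is the union
#' of the coverage disks rasterized on the mask grid. The normalized
#' quantities and herding indices follow the same definitions as the imaging
#' pipeline (see [herding_indices()]).
#'
#' @param scene an evolved `synthetic_scene`.
#' @param mask the `raster_mask` the scene lives on.
#' @return a `herding_result` (see [herding_indices()]).
#' @export
ground_truth_measurements <- function(scene, mask) {
  len_cnt <- 0; len_gap <- 0
  for (p in scene$processes) {
    v <- cpp_polyline_label_len(p, mask$cnt, mask$res,
                                mask$origin[["x"]], mask$origin[["y"]])
    len_gap <- len_gap + v[["gap"]]
    len_cnt <- len_cnt + v[["cnt"]]
  }
  ar <- area_raster(mask)
  g_cnt <- 0; g_gap <- 0
  gl <- scene$glial_regions
  if (!is.null(gl) && nrow(gl)) {
    gimg <- glia_coverage(gl, mask)
    g_cnt <- sum(gimg & mask$cnt) * mask$res^2
    g_gap <- sum(gimg & !mask$cnt) * mask$res^2
  }
  herding_indices(len_cnt, len_gap, g_cnt, g_gap, ar$A_CNT, ar$A_Si,
                  label = scene$label, div = scene$div)
}

# glial coverage on a grid: glia are confined by the branches -- gap glia
# disks clip at the branch boundary, branch glia disks stay on the branch
glia_coverage <- function(gl, mask) {
  on_cnt <- if ("on_cnt" %in% names(gl)) gl$on_cnt else rep(FALSE, nrow(gl))
  disks <- function(sel) {
    if (!any(sel)) return(matrix(FALSE, nrow(mask$cnt), ncol(mask$cnt)))
    cpp_fill_disks(nrow(mask$cnt), ncol(mask$cnt),
                   (gl$x[sel] - mask$origin[["x"]]) / mask$res,
                   (gl$y[sel] - mask$origin[["y"]]) / mask$res,
                   gl$r[sel] / mask$res)
  }
  (disks(!on_cnt) & !mask$cnt) | (disks(on_cnt) & mask$cnt)
}

#' Render a synthetic scene to fluorescence-like channels
#'
#' Processes are drawn as soft ~1-2 px curves, somas as small filled disks,
#' glial coverage as filled disks with multiplicative texture; Poisson shot
#' noise on a photon-count scale plus Gaussian read noise and a constant
#' background are added when `noise = TRUE`.
#'
#' @param scene an evolved `synthetic_scene`.
#' @param pixel_size um per pixel (0.32 emulates the study's camera).
#' @param noise add shot/read noise.
#' @param gain photon counts per unit rendered intensity.
#' @param background constant background counts.
#' @return list with `neuron`, `glia`, `nuclei` matrices (rows = y),
#'   `pixel_size` and `origin`.
#' @export
render_channels <- function(scene, pixel_size = 0.32, noise = TRUE,
                            gain = 2000, background = 100) {
  stopifnot(pixel_size > 0)
  b <- scene$bounds
  nx <- max(1L, round((b[["xmax"]] - b[["xmin"]]) / pixel_size))
  ny <- max(1L, round((b[["ymax"]] - b[["ymin"]]) / pixel_size))
  to_px <- function(m) cbind((m[, 1] - b[["xmin"]]) / pixel_size - 0.5,
                             (m[, 2] - b[["ymin"]]) / pixel_size - 0.5)
  set.seed(scene$rng_seed + 2L)
  neuron <- cpp_draw_polylines(ny, nx, lapply(scene$processes, to_px),
                               intensity = 1.0)
  s <- scene$somas
  nuclei <- matrix(0, ny, nx)
  if (!is.null(s) && nrow(s)) {
    sx <- (s$x - b[["xmin"]]) / pixel_size
    sy <- (s$y - b[["ymin"]]) / pixel_size
    nuc <- cpp_fill_disks(ny, nx, sx, sy, rep(2.5 / pixel_size, nrow(s)))
    nuclei <- nuclei + 1.0 * nuc
    # soma blobs: clustered somas render as one blob per cluster; the rest
    # as small individual disks; blobs clip at the edge of the surface the
    # cluster sits on (somas sit beside, not across, the branch walls)
    smask <- scene$mask
    if (!is.null(smask) &&
        (abs(smask$res - pixel_size) > 1e-9 || any(dim(smask$cnt) != c(ny, nx)))) {
      smask <- align_mask(smask, c(ny, nx), pixel_size)
    }
    draw_blobs <- function(x, y, r) {
      if (!length(x)) return(matrix(FALSE, ny, nx))
      cpp_fill_disks(ny, nx, (x - b[["xmin"]]) / pixel_size,
                     (y - b[["ymin"]]) / pixel_size, r / pixel_size)
    }
    ind <- s$kind == "neuron" & is.na(s$cluster) &
      !(if ("on_cnt" %in% names(s)) s$on_cnt else FALSE)
    cl <- scene$clusters
    cl_r <- if (!is.null(cl) && "r" %in% names(cl)) cl$r else rep(18, NROW(cl))
    gap_blobs <- draw_blobs(c(cl$x, s$x[ind]), c(cl$y, s$y[ind]),
                            c(cl_r, rep(5, sum(ind))))
    bc <- scene$branch_clusters
    cnt_blobs <- draw_blobs(bc$x, bc$y, bc$r)
    blobs <- if (!is.null(smask)) {
      (gap_blobs & !smask$cnt) | (cnt_blobs & smask$cnt)
    } else gap_blobs | cnt_blobs
    neuron <- neuron + 0.8 * blobs
  }
  glia <- matrix(0, ny, nx)
  gl <- scene$glial_regions
  if (!is.null(gl) && nrow(gl)) {
    gmask <- scene$mask
    if (!is.null(gmask) &&
        (abs(gmask$res - pixel_size) > 1e-9 || any(dim(gmask$cnt) != c(ny, nx)))) {
      gmask <- align_mask(gmask, c(ny, nx), pixel_size)
    }
    gd <- if (!is.null(gmask)) glia_coverage(gl, gmask) else
      cpp_fill_disks(ny, nx, (gl$x - b[["xmin"]]) / pixel_size,
                     (gl$y - b[["ymin"]]) / pixel_size, gl$r / pixel_size)
    glia[gd] <- 0.7
    glia <- glia * matrix(stats::runif(ny * nx, 0.8, 1.2), ny, nx)
  }
  finish <- function(img) {
    counts <- img * gain + background
    if (noise) {
      counts <- stats::rpois(length(counts), pmax(counts, 0)) +
        stats::rnorm(length(counts), 0, 10)
      counts <- matrix(pmax(counts, 0), ny, nx)
    }
    matrix(counts, ny, nx)
  }
  list(neuron = finish(neuron), glia = finish(glia), nuclei = finish(nuclei),
       pixel_size = pixel_size,
       origin = c(x = b[["xmin"]], y = b[["ymin"]]),
       label = scene$label, div = scene$div, rng_seed = scene$rng_seed)
}

#' Render a scene as overlapping field-of-view tiles
#'
#' The full field is rendered once and cut into `tile` x `tile` px tiles at
#' stride `floor(tile * (1 - overlap))`, emulating stitched microscope
#' acquisition; the field is padded with background to complete the grid.
#'
#' @inheritParams render_channels
#' @param tile tile side in pixels.
#' @param overlap fractional overlap between neighbouring tiles.
#' @return list with `tiles` (each holding the three channel matrices and
#'   its `row`/`col` indices) and a `manifest` (tile size, overlap, stride,
#'   grid, pixel size, padded full dimensions, origin, and an empty
#'   `excluded` list for field-of-view rejection).
#' @export
render_fov_tiles <- function(scene, pixel_size = 0.32, tile = 2048,
                             overlap = 0.10, noise = TRUE, ...) {
  ch <- render_channels(scene, pixel_size = pixel_size, noise = noise, ...)
  ny <- nrow(ch$neuron); nx <- ncol(ch$neuron)
  stride <- floor(tile * (1 - overlap))
  nr <- max(1L, ceiling((ny - tile) / stride) + 1L)
  nc <- max(1L, ceiling((nx - tile) / stride) + 1L)
  pady <- (nr - 1) * stride + tile
  padx <- (nc - 1) * stride + tile
  pad <- function(img) {
    out <- matrix(0, pady, padx)
    out[seq_len(ny), seq_len(nx)] <- img
    out
  }
  full <- lapply(ch[c("neuron", "glia", "nuclei")], pad)
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    ri <- (i - 1) * stride + seq_len(tile)
    ci <- (j - 1) * stride + seq_len(tile)
    tiles[[k]] <- list(neuron = full$neuron[ri, ci], glia = full$glia[ri, ci],
                       nuclei = full$nuclei[ri, ci], row = i, col = j)
  }
  manifest <- list(tile = tile, overlap = overlap, stride = stride,
                   grid = c(rows = nr, cols = nc), pixel_size = pixel_size,
                   full_dim = c(ny = pady, nx = padx),
                   origin = ch$origin, excluded = list(),
                   label = scene$label, div = scene$div)
  list(tiles = tiles, manifest = manifest)
}
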