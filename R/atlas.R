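# ---- basic triangulated geometry helpers ----

# icosahedron subdivided s times, vertices on the unit sphere
icosphere <- function(subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mid <- new.env(parent = emptyenv())
    newv <- list()
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      m <- mid[[k]]
      if (is.null(m)) {
        p <- (v[a, ] + v[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        newv[[length(newv) + 1]] <<- p
        m <- nv + length(newv)
        mid[[k]] <- m
      }
      m
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(verts = v, faces = f)
}

# n roughly uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

triangle_areas <- function(verts, faces) {
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c3 <- verts[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# angular cap membership on the unit sphere
in_cap <- function(u, dir, deg) {
  dir <- dir / sqrt(sum(dir^2))
  as.vector(u %*% dir) > cos(deg * pi / 180)
}

# ---- atlas configuration and construction ----

#' Atlas configuration
#'
#' Geometric parameters of the synthetic two-chamber atrial surface and the
#' torso electrode surface.  Lengths in cm.
#'
#' @param subdiv Icosphere subdivision level per chamber (4 gives 2562
#'   vertices per chamber).
#' @param torso_nodes Number of torso surface sample nodes.
#' @param n_foci Total ectopic focus count; `n_primary` of them form the
#'   marked subset used for fibrotic simulations.
#' @param n_foci_la Number of foci placed on the left atrium.
#' @param n_primary_la Left-atrial members of the primary subset.
#' @return Named list of parameters.
#' @export
atlas_config <- function(subdiv = 4, torso_nodes = 14157, n_foci = 57,
                         n_foci_la = 32, n_primary = 19, n_primary_la = 12) {
  list(subdiv = subdiv,
       la_center = c(2.5, 1.5, 0), la_radii = c(2.4, 2.2, 2.6),
       ra_center = c(-2.5, 0, 0), ra_radii = c(2.4, 2.4, 2.8),
       torso_nodes = torso_nodes,
       torso_center = c(0, 2, -4), torso_radii = c(17, 12, 30),
       n_foci = n_foci, n_foci_la = n_foci_la,
       n_primary = n_primary, n_primary_la = n_primary_la)
}

# ordered region labeling of one chamber given unit-sphere coordinates
label_la <- function(u) {
  reg <- rep("LA", nrow(u))
  reg[u[, 2] > 0.55] <- "LA_post"
  reg[u[, 3] < -0.55 & u[, 2] > 0.3] <- "CS"
  reg[u[, 3] < -0.82] <- "MVR"
  reg[in_cap(u, c(-0.5, -0.75, 0.35), 24)] <- "LAA"
  for (d in list(c(0.45, 0.8, 0.35), c(-0.45, 0.8, 0.35),
                 c(0.45, 0.8, -0.35), c(-0.45, 0.8, -0.35)))
    reg[in_cap(u, d, 15)] <- "PV"
  reg[in_cap(u, c(-0.95, 0.1, -0.2), 16)] <- "FO_ring"
  reg[in_cap(u, c(-0.95, 0.1, -0.2), 8)] <- "FO"
  reg
}

label_ra <- function(u) {
  reg <- rep("RA", nrow(u))
  reg[u[, 2] < -0.5 & u[, 3] < 0.4] <- "PM"
  reg[u[, 3] > 0.6 | u[, 1] > 0.85] <- "CT_BB"
  reg[u[, 3] < -0.82] <- "TVR"
  reg[in_cap(u, c(-0.4, -0.8, 0.45), 24)] <- "RAA"
  reg[in_cap(u, c(0.95, 0.1, -0.2), 16)] <- "FO_ring"
  reg[in_cap(u, c(0.95, 0.1, -0.2), 8)] <- "FO"
  reg
}

# conduction speed (mm/ms) for an atlas region label
region_speed <- function(region) {
  tab <- atrial_region_table()
  alias <- c(LA_post = "LA", FO_ring = "LA")
  base <- ifelse(region %in% names(alias), alias[region], region)
  cv <- tab$cv_l[match(base, tab$region)] / 100  # cm/s -> mm/ms
  cv[base == "FO"] <- 0
  cv
}

# farthest-point sampling on a vertex subset (Euclidean, deterministic
# given the seeded start vertex)
fps_sample <- function(verts, pool, n, rng_seed) {
  sel <- integer(n)
  sel[1] <- with_seed(rng_seed, sample(pool, 1))
  d <- sqrt(rowSums((verts[pool, , drop = FALSE] -
                     matrix(verts[sel[1], ], length(pool), 3,
                            byrow = TRUE))^2))
  for (k in seq_len(n - 1)) {
    sel[k + 1] <- pool[which.max(d)]
    d2 <- sqrt(rowSums((verts[pool, , drop = FALSE] -
                        matrix(verts[sel[k + 1], ], length(pool), 3,
                               byrow = TRUE))^2))
    d <- pmin(d, d2)
  }
  sel
}

# nearest cross-chamber vertex pairs between two vertex sets (may return
# fewer than n_pairs on coarse meshes)
connect_pairs <- function(verts, set_a, set_b, n_pairs) {
  pairs <- NULL
  used_a <- used_b <- integer(0)
  for (k in seq_len(n_pairs)) {
    best <- c(NA, NA, Inf)
    for (a in setdiff(set_a, used_a)) {
      cand_b <- setdiff(set_b, used_b)
      if (!length(cand_b)) break
      d <- sqrt(rowSums((verts[cand_b, , drop = FALSE] -
                         matrix(verts[a, ], length(cand_b), 3,
                                byrow = TRUE))^2))
      j <- which.min(d)
      if (d[j] < best[3]) best <- c(a, cand_b[j], d[j])
    }
    if (!is.finite(best[3])) break
    pairs <- rbind(pairs, best[1:2])
    used_a <- c(used_a, best[1]); used_b <- c(used_b, best[2])
  }
  if (is.null(pairs)) matrix(0L, 0, 2) else
    matrix(as.integer(pairs), ncol = 2)
}

#' Build the synthetic atrial + torso atlas
#'
#' Constructs a reduced two-chamber atrial surface (two joined ellipsoidal
#' shells with labeled regions: posterior left-atrial wall, four pulmonary
#' vein ostia, appendages, valve rings, fossa ovalis and its ring, coronary
#' sinus, crista terminalis / Bachmann's bundle, pectinate muscles), a
#' torso electrode surface, and the ectopic focus sets: `n_foci` foci in
#' total of which a marked subset of `n_primary` is used for fibrotic
#' simulations.  Inter-atrial conduction is carried by explicit connection
#' edges (Bachmann's bundle, fossa ovalis rim, coronary sinus).
#'
#' This surface is a deliberately simplified stand-in for an anatomical
#' atrial mesh: it carries the region labels, conduction heterogeneity and
#' two-chamber topology the pipeline needs, at desk scale.
#'
#' @param config From [atlas_config()].
#' @param rng_seed Integer seed (focus placement start).
#' @return Object of class `atrial_atlas`.
#' @export
build_atlas <- function(config = atlas_config(), rng_seed = 1) {
  ico <- icosphere(config$subdiv)
  u <- ico$verts
  nvc <- nrow(u)

  la_v <- sweep(u %*% diag(config$la_radii), 2, config$la_center, "+")
  ra_v <- sweep(u %*% diag(config$ra_radii), 2, config$ra_center, "+")
  verts <- rbind(la_v, ra_v)
  faces <- rbind(ico$faces, ico$faces + nvc)
  chamber <- rep(c("LA", "RA"), each = nvc)
  # RA labels are defined with +x pointing toward the septum (mirror)
  ur <- u; ur[, 1] <- -ur[, 1]
  region <- c(label_la(u), label_ra(ur))
  speed <- region_speed(region)

  la_idx <- seq_len(nvc); ra_idx <- nvc + seq_len(nvc)
  bb <- connect_pairs(verts,
                      la_idx[in_cap(u, c(-0.8, -0.2, 0.55), 20)],
                      ra_idx[in_cap(ur, c(0.8, -0.2, 0.55), 20)], 2)
  fo <- connect_pairs(verts, la_idx[region[la_idx] == "FO_ring"],
                      ra_idx[region[ra_idx] == "FO_ring"], 3)
  cs <- connect_pairs(verts, la_idx[region[la_idx] == "CS"],
                      ra_idx[in_cap(ur, c(0.8, 0.4, -0.45), 25)], 2)
  extra_edges <- rbind(bb, fo, cs)
  if (nrow(bb) == 0 || nrow(fo) == 0 || nrow(cs) == 0)
    warning("some inter-atrial connections could not be placed ",
            "(mesh too coarse)")
  conn_type <- rep(c("BB", "FO", "CS"), c(nrow(bb), nrow(fo), nrow(cs)))

  face_area <- triangle_areas(verts, faces)
  vert_area <- numeric(nrow(verts))
  for (k in 1:3) {
    ta <- tapply(face_area / 3, faces[, k], sum)
    vert_area[as.integer(names(ta))] <- vert_area[as.integer(names(ta))] + ta
  }

  # foci: farthest-point sampling per chamber on conducting vertices
  ok_la <- la_idx[speed[la_idx] > 0]
  ok_ra <- ra_idx[speed[ra_idx] > 0]
  n_ra <- config$n_foci - config$n_foci_la
  f_la <- fps_sample(verts, ok_la, config$n_foci_la, rng_seed)
  f_ra <- fps_sample(verts, ok_ra, n_ra, rng_seed + 1)
  foci <- data.frame(
    id = c(paste0("LA", seq_len(config$n_foci_la)),
           paste0("RA", seq_len(n_ra))),
    vertex = c(f_la, f_ra),
    region = region[c(f_la, f_ra)],
    chamber = rep(c("LA", "RA"), c(config$n_foci_la, n_ra)),
    primary = c(seq_len(config$n_foci_la) <= config$n_primary_la,
                seq_len(n_ra) <= (config$n_primary - config$n_primary_la)),
    stringsAsFactors = FALSE)

  tv <- sweep(fibonacci_sphere(config$torso_nodes) %*%
                diag(config$torso_radii), 2, config$torso_center, "+")

  out <- structure(list(verts = verts, faces = faces, chamber = chamber,
                        region = region, speed = speed,
                        extra_edges = extra_edges, conn_type = conn_type,
                        face_area = face_area, vert_area = vert_area,
                        foci = foci, torso = list(verts = tv),
                        config = config, rng_seed = rng_seed),
                   class = "atrial_atlas")
  out$vadj <- vertex_adjacency(out)
  out
}

#' @export
print.atrial_atlas <- function(x, ...) {
  cat(sprintf("atrial_atlas: %d vertices, %d faces (LA+RA), %d torso nodes\n",
              nrow(x$verts), nrow(x$faces), nrow(x$torso$verts)))
  cat(sprintf("  %d foci (%d primary), %d inter-atrial connection edges\n",
              nrow(x$foci), sum(x$foci$primary), nrow(x$extra_edges)))
  cat("  regions:", paste(sort(unique(x$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Fibrosis growth domain of one atlas chamber
#'
#' Face-element domain (edge adjacency, face areas, face region labels) of
#' the given chamber, for the stochastic fibrosis generator.
#'
#' @param atlas An `atrial_atlas`.
#' @param chamber `"LA"` or `"RA"`.
#' @return A [fibrosis_domain()]; attribute `face_ids` maps elements to
#'   atlas face rows.
#' @export
surface_domain <- function(atlas, chamber = "LA") {
  fch <- atlas$chamber[atlas$faces[, 1]]
  fid <- which(fch == chamber)
  f <- atlas$faces[fid, , drop = FALSE]
  # adjacency via shared edges
  ek <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))
  keys <- ek(edges[, 1], edges[, 2])
  face_of <- rep(seq_len(nrow(f)), 3)
  sp <- split(face_of, keys)
  adj <- vector("list", nrow(f))
  for (p in sp) if (length(p) == 2) {
    adj[[p[1]]] <- c(adj[[p[1]]], p[2])
    adj[[p[2]]] <- c(adj[[p[2]]], p[1])
  }
  # face region: majority vertex label, ties to the first
  freg <- apply(matrix(atlas$region[f], ncol = 3), 1, function(r)
    names(sort(table(r), decreasing = TRUE))[1])
  dom <- fibrosis_domain(adj, atlas$face_area[fid], freg)
  attr(dom, "face_ids") <- fid
  dom
}

# per-vertex fibrosis classification from a face-element model:
#   status 0 healthy, 1 fibrotic boundary (slowed), 2 fibrotic interior
#   (blocked: local fibrotic width of three elements or more), plus the set
#   of healthy vertices adjacent to fibrosis (amplitude attenuation)
vertex_fibrosis <- function(atlas, fibrosis) {
  nv <- nrow(atlas$verts)
  if (is.null(fibrosis))
    return(list(status = integer(nv), adjacent = logical(nv)))
  fid <- attr(fibrosis, "face_ids")
  if (is.null(fid))
    stop("fibrosis model does not map to atlas faces (grow it on a ",
         "surface_domain of this atlas)")
  fib_faces <- fid[fibrosis$element_labels]
  area_f <- numeric(nv); area_t <- numeric(nv)
  for (k in 1:3) {
    t1 <- tapply(atlas$face_area / 3, atlas$faces[, k], sum)
    area_t[as.integer(names(t1))] <- area_t[as.integer(names(t1))] + t1
    if (length(fib_faces)) {
      t2 <- tapply(atlas$face_area[fib_faces] / 3,
                   atlas$faces[fib_faces, k], sum)
      area_f[as.integer(names(t2))] <- area_f[as.integer(names(t2))] + t2
    }
  }
  fibv <- area_t > 0 & area_f / pmax(area_t, 1e-12) >= 0.5
  adj <- vertex_adjacency(atlas)
  status <- integer(nv)
  has_healthy_nb <- vapply(seq_len(nv), function(v)
    any(!fibv[adj[[v]]]), logical(1))
  status[fibv & has_healthy_nb] <- 1L
  status[fibv & !has_healthy_nb] <- 2L
  adjacent <- !fibv & vapply(seq_len(nv), function(v)
    any(fibv[adj[[v]]]), logical(1))
  list(status = status, adjacent = adjacent)
}

# vertex adjacency list of the atlas mesh (cached on the atlas)
vertex_adjacency <- function(atlas) {
  if (!is.null(atlas$vadj)) return(atlas$vadj)
  nv <- nrow(atlas$verts)
  f <- atlas$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1], atlas$extra_edges, atlas$extra_edges[, 2:1])
  adj <- split(e[, 2], e[, 1])
  out <- vector("list", nv)
  out[as.integer(names(adj))] <- lapply(adj, unique)
  out
}

#' Organ-scale activation map by anisotropic fast marching
#'
#' Computes the local activation time (LAT) from an ectopic focus over the
#' atlas surface by fast marching with per-vertex slowness (the eikonal
#' surrogate for tissue-scale propagation).  Fibrotic vertices at the patch
#' boundary are slowed by the factor calibrated on the slab experiments;
#' fibrotic vertices whose whole neighbourhood is fibrotic (local fibrotic
#' width of three elements-equivalent or more) are blocked and never
#' activate.
#'
#' @param atlas An `atrial_atlas`.
#' @param focus Focus id (e.g. `"LA1"`), focus row, or vertex index.
#' @param fibrosis Optional `fibrosis_model` on [surface_domain()].
#' @param slow_factor Speed multiplier of boundary fibrotic vertices.
#' @return List with `lat` (ms per vertex, `NA` unreached), `status`
#'   (per-vertex fibrosis status), `attenuation` (amplitude factor per
#'   vertex), `focus_vertex`.
#' @export
eikonal_activation <- function(atlas, focus, fibrosis = NULL,
                               slow_factor = 0.1, vf = NULL) {
  fv <- resolve_focus(atlas, focus)
  vf <- vf %||% vertex_fibrosis(atlas, fibrosis)
  speed <- atlas$speed
  speed[vf$status == 1L] <- speed[vf$status == 1L] * slow_factor
  speed[vf$status == 2L] <- 0
  slowness <- ifelse(speed > 0, 1 / speed, Inf)
  # a focal trigger excites a small tissue neighbourhood, not a point: if
  # the focus vertex itself is blocked, capture still succeeds from
  # conducting tissue in its one-ring; it fails only when the whole
  # neighbourhood is blocked
  src <- fv
  if (!is.finite(slowness[fv])) {
    ring <- vertex_adjacency(atlas)[[fv]]
    src <- ring[is.finite(slowness[ring])]
    if (!length(src)) {
      cond <- structure(
        class = c("no_capture", "error", "condition"),
        list(message = paste0("no capture: focus vertex ", fv,
                              " and its neighbourhood lie in blocked ",
                              "fibrotic tissue"),
             call = sys.call()))
      stop(cond)
    }
  }
  lat <- cpp_fmm(atlas$verts * 10, atlas$faces - 1L, slowness,
                 atlas$extra_edges - 1L, as.integer(src) - 1L,
                 rep(0, length(src)))
  atten <- rep(1, nrow(atlas$verts))
  atten[vf$status == 1L | vf$adjacent] <- 0.578  # fibrosis-adjacent class
  list(lat = lat, status = vf$status, attenuation = atten,
       focus_vertex = fv)
}

resolve_focus <- function(atlas, focus) {
  if (is.character(focus)) {
    i <- match(focus, atlas$foci$id)
    if (is.na(i)) stop("unknown focus id: ", focus)
    atlas$foci$vertex[i]
  } else if (is.data.frame(focus)) focus$vertex[1]
  else as.integer(focus)
}

#' Synthesize per-vertex transmembrane signals from a LAT map
#'
#' Each reached vertex plays the action-potential template shifted to its
#' activation time; unreached vertices stay at the resting potential.
#' Amplitude attenuation factors (fibrosis-adjacent tissue) scale the
#' deviation from rest.
#'
#' @param lat LAT map (ms, `NA` for unreached).
#' @param ap_template An `ap_trace` (or list with `t`, `V`).
#' @param window_ms Signal window `(t0, t1)` in ms; default
#'   `c(0, max(lat) + 350)`.
#' @param attenuation Per-vertex amplitude factors (default 1).
#' @param sample_ms Sampling interval (1 kHz default).
#' @return List with `V` (vertex x time matrix, mV), `t` (ms), `rmp`.
#' @export
synthesize_transmembrane <- function(lat, ap_template, window_ms = NULL,
                                     attenuation = 1, sample_ms = 1) {
  tpl_t <- ap_template$t; tpl_v <- ap_template$V
  rmp <- tpl_v[1]
  if (is.null(window_ms))
    window_ms <- c(0, max(lat, na.rm = TRUE) + 350)
  t <- seq(window_ms[1], window_ms[2], by = sample_ms)
  end_ok <- abs(tpl_v[length(tpl_v)] - rmp) < 5
  if (max(tpl_t) < diff(window_ms) && !end_ok)
    stop("action-potential template shorter than the simulation window ",
         "and not repolarized at its end")
  nv <- length(lat)
  att <- rep_len(attenuation, nv)
  V <- matrix(rmp, nv, length(t))
  reached <- which(!is.na(lat))
  if (length(reached)) {
    # one interpolation over all (vertex, time) pairs at once
    tv <- outer(-lat[reached], t, "+")
    vi <- matrix(approx(tpl_t, tpl_v, pmax(as.vector(tv), 0),
                        rule = 2)$y, nrow(tv))
    vi[tv < 0] <- rmp
    V[reached, ] <- rmp + (vi - rmp) * att[reached]
  }
  list(V = V, t = t, rmp = rmp)
}

#' Assemble an activation dataset (models M0..M5)
#'
#' `"M0"` runs the full focus set on the fibrosis-free atlas.  `"Mk"`
#' (k = 1..5) runs the primary focus subset for every fibrosis case at
#' stages 1..k, excluding runs whose focus lies in blocked fibrotic tissue
#' ("no capture").
#'
#' @param atlas An `atrial_atlas`.
#' @param library Fibrosis case library from [build_case_library()] on
#'   [surface_domain()] (required for M1..M5).
#' @param model `"M0"` .. `"M5"`.
#' @return Object of class `activation_dataset`: `manifest` (run id, focus,
#'   case, stage, excluded), `lat` (vertex x run matrix), `attenuation`
#'   (vertex x run), and bookkeeping `counts`.
#' @export
build_dataset <- function(atlas, library = NULL,
                          model = c("M0", "M1", "M2", "M3", "M4", "M5")) {
  model <- match.arg(model)
  k <- as.integer(substring(model, 2))
  nv <- nrow(atlas$verts)
  if (k == 0) {
    plan <- data.frame(focus = atlas$foci$id, case = NA_integer_,
                       stage = NA_integer_, stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(library))
    prim <- atlas$foci$id[atlas$foci$primary]
    cases <- sort(unique(vapply(library, `[[`, 0L, "case_id")))
    plan <- expand.grid(focus = prim, case = cases, stage = seq_len(k),
                        stringsAsFactors = FALSE)
  }
  n <- nrow(plan)
  lat <- matrix(NA_real_, nv, n)
  att <- matrix(1, nv, n)
  excluded <- logical(n)
  # group runs by fibrosis model so its vertex classification is computed once
  key <- if (k > 0) paste(plan$case, plan$stage) else rep("none", n)
  for (kk in unique(key)) {
    rows <- which(key == kk)
    fib <- NULL
    if (k > 0) {
      sel <- which(vapply(library, function(m)
        m$case_id == plan$case[rows[1]] &&
          m$stage == plan$stage[rows[1]], logical(1)))
      fib <- library[[sel]]
    }
    vf <- vertex_fibrosis(atlas, fib)
    for (i in rows) {
      res <- tryCatch(eikonal_activation(atlas, plan$focus[i], fib, vf = vf),
                      no_capture = function(e) NULL)
      if (is.null(res)) { excluded[i] <- TRUE; next }
      lat[, i] <- res$lat
      att[, i] <- res$attenuation
    }
  }
  manifest <- data.frame(run = seq_len(n), focus = plan$focus,
                         case = plan$case, stage = plan$stage,
                         excluded = excluded, stringsAsFactors = FALSE)
  structure(list(manifest = manifest,
                 lat = lat[, !excluded, drop = FALSE],
                 attenuation = att[, !excluded, drop = FALSE],
                 model = model,
                 counts = list(candidates = n, excluded = sum(excluded),
                               samples = n - sum(excluded))),
            class = "activation_dataset")
}

#' @export
print.activation_dataset <- function(x, ...) {
  cat(sprintf("activation_dataset %s: %d samples (%d candidates, %d excluded)\n",
              x$model, x$counts$samples, x$counts$candidates,
              x$counts$excluded))
  invisible(x)
}
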