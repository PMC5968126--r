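#' Growth domain for the fibrosis generator
#'
#' The stochastic fibrosis generator operates on an abstract element domain:
#' an adjacency structure, per-element sizes (area or volume) and region
#' labels.  `fibrosis_domain()` builds one from parts;
#' `lattice_domain()` builds the domain of a 2D voxel slab (4-neighbour
#' lattice, a single `"interior"` region); `surface_domain()` builds the
#' face domain of a triangulated atrial surface restricted to one chamber.
#'
#' @param adjacency List of integer vectors: neighbours of each element.
#' @param size Per-element size (same units throughout; fractions are
#'   size-weighted).
#' @param region Per-element region label (seeding strata).
#' @return Object of class `fibrosis_domain`.
#' @export
fibrosis_domain <- function(adjacency, size, region) {
  n <- length(adjacency)
  stopifnot(length(size) == n, length(region) == n, all(size > 0))
  structure(list(n = n, adjacency = adjacency, size = size,
                 region = as.character(region)),
            class = "fibrosis_domain")
}

#' @rdname fibrosis_domain
#' @param nx,ny Lattice dimensions.
#' @export
lattice_domain <- function(nx, ny) {
  n <- nx * ny
  ix <- (seq_len(n) - 1L) %% nx + 1L
  iy <- (seq_len(n) - 1L) %/% nx + 1L
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    if (ix[i] > 1) nb <- c(nb, i - 1L)
    if (ix[i] < nx) nb <- c(nb, i + 1L)
    if (iy[i] > 1) nb <- c(nb, i - nx)
    if (iy[i] < ny) nb <- c(nb, i + nx)
    adj[[i]] <- nb
  }
  fibrosis_domain(adj, rep(1, n), rep("interior", n))
}

#' Utah staging of left-atrial fibrosis burden
#'
#' Quartile bands of the fibrotic-to-atrial volume ratio: stage I below
#' 8.1%, stage II in \[8.1%, 16%), stage III in \[16%, 21%), stage IV at or
#' above 21%.  Band boundaries are half-open with the lower bound belonging
#' to the upper stage.  Stages IV and V share the top quartile and are
#' distinguished by the generator's growth target, not by the fraction.
#'
#' @param fraction Fibrotic volume fraction in \[0, 1\].
#' @return Stage label `"I"`..`"IV"`.
#' @export
#' @examples
#' classify_utah_stage(c(0.05, 0.081, 0.18, 0.3))
classify_utah_stage <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  cut(fraction, c(-Inf, 0.081, 0.16, 0.21, Inf), right = FALSE,
      labels = c("I", "II", "III", "IV"))
}

#' Default growth targets of the five stages
#'
#' Fibrotic-fraction targets for stages I-V spanning roughly 2% to 40%,
#' one per stage, with two targets inside the shared top quartile (IV, V).
#'
#' @return Numeric vector of length 5.
#' @export
utah_stage_targets <- function() c(0.02, 0.12, 0.18, 0.28, 0.40)

#' Place fibrosis seeds on a domain
#'
#' Draws `n_seeds` distinct elements, allocating seeds to regions in
#' proportion to `region_weights` and uniformly within each region.
#'
#' @param domain A [fibrosis_domain()].
#' @param n_seeds Number of seeds.
#' @param region_weights Named non-negative weights over region labels.
#' @param rng_seed Integer seed (reproducible draws).
#' @return Integer element indices (the seeds).
#' @export
place_seeds <- function(domain, n_seeds = 50,
                        region_weights = c(PV = 1, CS = 1, FO_ring = 1,
                                           LA_post = 1),
                        rng_seed = 1) {
  stopifnot(inherits(domain, "fibrosis_domain"), n_seeds >= 0)
  if (n_seeds == 0) return(integer(0))
  w <- region_weights[region_weights > 0]
  for (r in names(w))
    if (!any(domain$region == r))
      stop("weighted region has no elements on the domain: ", r)
  with_seed(rng_seed, {
    # largest-remainder allocation of seeds to regions
    quota <- n_seeds * w / sum(w)
    n_r <- floor(quota)
    rem <- n_seeds - sum(n_r)
    if (rem > 0) {
      o <- order(quota - n_r, decreasing = TRUE)
      n_r[o[seq_len(rem)]] <- n_r[o[seq_len(rem)]] + 1
    }
    seeds <- integer(0)
    for (r in names(w)) {
      pool <- setdiff(which(domain$region == r), seeds)
      k <- min(n_r[[r]], length(pool))
      if (k > 0)
        seeds <- c(seeds, sample(pool, k,
                                 prob = domain$size[pool]))
    }
    sort(seeds)
  })
}

#' Grow patchy fibrosis by stochastic region growing
#'
#' Iterative frontier expansion from the seeds: each iteration adds every
#' healthy element adjacent to the fibrotic set, then reverts each newly
#' added contour element back to healthy with probability `drop_prob`,
#' producing irregular patch shapes that can enclose surviving healthy
#' islands.  Growth stops at the first iteration where the size-weighted
#' fibrotic fraction reaches `target_fraction`.  Passing a previous
#' `fibrosis_model` as `init` continues growth, so successive stages nest.
#'
#' @param domain A [fibrosis_domain()].
#' @param seeds Seed elements from [place_seeds()].
#' @param target_fraction Target fibrotic fraction in (0, 1).
#' @param drop_prob Contour reversion probability in \[0, 1).
#' @param rng_seed Integer seed.
#' @param init Optional `fibrosis_model` to continue growing from.
#' @param case_id,stage Metadata stored on the result.
#' @return Object of class `fibrosis_model` with `element_labels` (logical),
#'   `fraction`, `stage`, `case_id`, `seeds`.
#' @export
grow_fibrosis <- function(domain, seeds, target_fraction, drop_prob = 0.3,
                          rng_seed = 1, init = NULL, case_id = NA_integer_,
                          stage = NA_integer_) {
  stopifnot(inherits(domain, "fibrosis_domain"),
            target_fraction > 0, target_fraction < 1,
            drop_prob >= 0, drop_prob < 1, length(seeds) >= 1)
  total <- sum(domain$size)
  fib <- logical(domain$n)
  if (!is.null(init)) fib[init$element_labels] <- TRUE
  fib[seeds] <- TRUE
  frac <- sum(domain$size[fib]) / total
  # advance the RNG stream past the iterations a previous stage consumed so
  # continued growth is reproducible from (rng_seed, stage) alone
  iter0 <- if (is.null(init)) 0L else attr(init, "iterations") %||% 0L
  it <- 0L
  with_seed(rng_seed, {
    while (it < iter0) {  # replay: consume identical RNG draws
      it <- it + 1L
      runif(attr(init, "draws")[it])
    }
    draws <- if (is.null(init)) integer(0) else attr(init, "draws")
    while (frac < target_fraction) {
      it <- it + 1L
      frontier <- setdiff(unique(unlist(domain$adjacency[fib])),
                          which(fib))
      if (!length(frontier))
        stop(sprintf(paste0("fibrosis target unreachable: achieved ",
                            "fraction %.3f of target %.3f"),
                     frac, target_fraction))
      u <- runif(length(frontier))
      draws <- c(draws, length(frontier))
      keep <- frontier[u >= drop_prob | frontier %in% seeds]
      fib[keep] <- TRUE
      frac <- sum(domain$size[fib]) / total
    }
    structure(list(element_labels = fib, fraction = frac,
                   case_id = case_id, stage = stage, seeds = seeds,
                   target = target_fraction, drop_prob = drop_prob,
                   rng_seed = rng_seed),
              class = "fibrosis_model", iterations = it, draws = draws,
              face_ids = attr(domain, "face_ids"))
  })
}

#' @export
print.fibrosis_model <- function(x, ...) {
  cat(sprintf("fibrosis_model: case %s stage %s, fraction %.1f%% (%d elements)\n",
              x$case_id, x$stage, 100 * x$fraction, sum(x$element_labels)))
  invisible(x)
}

#' Build the 5-case x 5-stage fibrosis library
#'
#' For each case, seeds are placed once and fibrosis is grown incrementally
#' through the five stage targets, so within a case the stages nest.
#'
#' @param domain A [fibrosis_domain()].
#' @param n_cases Number of random distributions.
#' @param stage_targets Increasing fraction targets, one per stage.
#' @param drop_prob Contour reversion probability.
#' @param rng_base Base integer seed; case `c` uses `rng_base + c`.
#' @param n_seeds,region_weights Passed to [place_seeds()].
#' @return List of `n_cases * 5` `fibrosis_model` objects, ordered case by
#'   case, stage by stage.
#' @export
build_case_library <- function(domain, n_cases = 5,
                               stage_targets = utah_stage_targets(),
                               drop_prob = 0.3, rng_base = 100,
                               n_seeds = 50,
                               region_weights = c(PV = 1, CS = 1,
                                                  FO_ring = 1, LA_post = 1)) {
  stopifnot(all(diff(stage_targets) > 0))
  out <- vector("list", n_cases * length(stage_targets))
  k <- 0
  for (cs in seq_len(n_cases)) {
    seeds <- place_seeds(domain, n_seeds, region_weights,
                         rng_seed = rng_base + cs)
    fib <- NULL
    for (st in seq_along(stage_targets)) {
      fib <- grow_fibrosis(domain, seeds, stage_targets[st], drop_prob,
                           rng_seed = rng_base + 50L + cs, init = fib,
                           case_id = cs, stage = st)
      k <- k + 1
      out[[k]] <- fib
    }
  }
  out
}

# connected fibrotic patches (for invariants / diagnostics)
fibrosis_components <- function(domain, model) {
  fib <- which(model$element_labels)
  comp <- rep(NA_integer_, domain$n)
  cid <- 0L
  for (s in fib) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- domain$adjacency[[v]]
      nb <- nb[model$element_labels[nb] & is.na(comp[nb])]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}
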