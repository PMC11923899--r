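# Synthetic layer-stratified neuron scenes with planted enrichment, used as
# ground truth for every pipeline stage. Positions are homogeneous Poisson;
# class labels i.i.d. Bernoulli; subclass labels i.i.d. from per-class
# mixtures. All randomness flows through one seeded RNG stream per call, and
# the global RNG state is restored afterwards.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# child seeds derived from one parent seed; kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(index)) %% 2147483647)
}

default_subclass_mix <- function() {
  list(
    excitatory = c(L2 = 0.2, L2.3 = 0.2, L2.3.4 = 0.2, L3.4 = 0.2, L3.4.5 = 0.2),
    inhibitory = c(PV_CHC = 0.4, RELN = 0.3, OTHER_IN = 0.3)
  )
}

#' Configuration for a synthetic cortical scene
#'
#' Describes one rectangular section: extent in micrometres, a homogeneous
#' background intensity, the inhibitory class fraction, per-class subclass
#' mixtures, optional horizontal layer bands and optional vertical region
#' strips.
#'
#' @param width,height extent of the section in micrometres.
#' @param lambda background intensity in cells per square millimetre.
#' @param p_inh inhibitory fraction in (0, 1); the default 0.15 mirrors the
#'   roughly 15 percent share of inhibitory neurons among cortical neurons.
#' @param n_layers number of equal-height horizontal bands mapped to cortical
#'   layers `1..n_layers` (top band = layer 1); must be between 1 and 6.
#' @param subclass_mix named list with probability vectors `excitatory` and
#'   `inhibitory` (names = subclass labels, values sum to 1). Default: five
#'   layer-marker excitatory types (L2, L2.3, L2.3.4, L3.4, L3.4.5) and three
#'   inhibitory types (PV_CHC, RELN, OTHER_IN), uniform within class.
#' @param regions optional data.frame with columns `region`, `xmin`, `xmax`
#'   whose intervals partition `[0, width)`; `NULL` = single region `"R1"`.
#' @param section_id section label for all generated cells.
#' @param seed integer seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width, height, lambda = 500, p_inh = 0.15,
                         n_layers = 1L, subclass_mix = NULL, regions = NULL,
                         section_id = "S1", seed = 1L) {
  if (width <= 0 || height <= 0) stop("scene extent must have positive area")
  if (lambda <= 0) stop("lambda must be positive")
  if (!(p_inh >= 0 && p_inh < 1)) stop("p_inh must lie in [0, 1)")
  if (n_layers < 1L || n_layers > 6L) stop("n_layers must be in 1..6")
  if (is.null(subclass_mix)) subclass_mix <- default_subclass_mix()
  for (cls in CLASS_LEVELS) {
    p <- subclass_mix[[cls]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8) {
      stop("subclass_mix$", cls, " must be a named probability vector summing to 1")
    }
  }
  if (is.null(regions)) {
    regions <- data.frame(region = "R1", xmin = 0, xmax = width)
  }
  regions <- regions[order(regions$xmin), , drop = FALSE]
  if (abs(regions$xmin[1]) > 1e-9 ||
      abs(regions$xmax[nrow(regions)] - width) > 1e-9 ||
      (nrow(regions) > 1L &&
       any(abs(regions$xmax[-nrow(regions)] - regions$xmin[-1]) > 1e-9))) {
    stop("region intervals must partition [0, width)")
  }
  structure(list(width = width, height = height, lambda = lambda,
                 p_inh = p_inh, n_layers = as.integer(n_layers),
                 subclass_mix = subclass_mix, regions = regions,
                 section_id = section_id, seed = as.integer(seed)),
            class = "scene_config")
}

draw_subclasses <- function(cls, mix) {
  out <- character(length(cls))
  for (cl in CLASS_LEVELS) {
    idx <- which(cls == cl)
    if (length(idx) > 0L) {
      p <- mix[[cl]]
      out[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
  }
  out
}

scene_layer_of <- function(config, y) {
  band <- config$height / config$n_layers
  b <- pmax(0L, pmin(floor(y / band), config$n_layers - 1L)) # band from bottom
  as.integer(config$n_layers - b) # top band (largest y) = layer 1
}

scene_region_of <- function(config, x) {
  idx <- findInterval(x, config$regions$xmin)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(config$regions)] <- nrow(config$regions)
  config$regions$region[idx]
}

make_cells <- function(config, n, x, y, cls, id_offset = 0L) {
  subclass <- draw_subclasses(cls, config$subclass_mix)
  cell_table(data.frame(
    cell_id = sprintf("c%07d", id_offset + seq_len(n)),
    x = x, y = y,
    section_id = config$section_id,
    layer = scene_layer_of(config, y),
    region = scene_region_of(config, x),
    class = cls,
    subclass = subclass,
    stringsAsFactors = FALSE
  ), subclass_vocab = lapply(config$subclass_mix, names))
}

#' Generate a homogeneous background scene
#'
#' Draws `N ~ Poisson(lambda * area)` cells uniformly over the extent
#' (complete spatial randomness), labels each inhibitory with probability
#' `p_inh` and assigns subclasses i.i.d. from the per-class mixtures. The
#' draw order (count, x, y, class, subclass) is fixed so a seed pins the
#' scene exactly.
#'
#' @param config a [scene_config()].
#' @return A [cell_table()].
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  area_mm2 <- config$width * config$height / 1e6
  with_seed(config$seed, {
    n <- rpois(1L, config$lambda * area_mm2)
    x <- runif(n, 0, config$width)
    y <- runif(n, 0, config$height)
    cls <- ifelse(rbinom(n, 1L, config$p_inh) == 1L, "inhibitory", "excitatory")
    make_cells(config, n, x, y, cls)
  })
}

#' Describe a planted enriched disc
#'
#' @param center numeric length-2 centre (x, y) in micrometres.
#' @param radius disc radius in micrometres.
#' @param class class to enrich inside the disc.
#' @param fraction fraction of in-disc cells carrying the enriched class
#'   after resampling, in (0, 1].
#' @param density_mult optional density multiplier (>= 1); extra cells are
#'   added inside the disc at rate `(density_mult - 1) * lambda`.
#' @param subclass_mix optional named-list override of the in-disc subclass
#'   mixtures (same shape as in [scene_config()]).
#' @return A `planted_cluster` list.
#' @export
planted_cluster <- function(center, radius, class = "inhibitory",
                            fraction = 0.5, density_mult = 1,
                            subclass_mix = NULL) {
  class <- match.arg(class, CLASS_LEVELS)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  if (radius <= 0) stop("radius must be positive")
  if (density_mult < 1) stop("density_mult must be >= 1")
  structure(list(center = as.numeric(center), radius = radius, class = class,
                 fraction = fraction, density_mult = density_mult,
                 subclass_mix = subclass_mix),
            class = "planted_cluster")
}

in_disc <- function(x, y, disc) {
  (x - disc$center[1])^2 + (y - disc$center[2])^2 <= disc$radius^2
}

#' Plant enriched discs into a background scene
#'
#' Inside each disc the class labels of existing cells are resampled so the
#' enriched class occurs with the disc's `fraction` (positions are untouched,
#' isolating composition from density); subclasses are redrawn to match the
#' possibly overridden mixture. A `density_mult > 1` additionally adds
#' Poisson extra cells inside the disc. Cells outside every disc are
#' untouched. Overlapping discs that enrich opposite classes are rejected so
#' the ground truth stays unambiguous.
#'
#' @param table background [cell_table()] (typically from
#'   [generate_background()]).
#' @param planted list of [planted_cluster()] objects.
#' @param config the [scene_config()] the background was drawn from.
#' @param seed integer seed for the resampling stream.
#' @return List with elements `cells` (the modified `cell_table`) and
#'   `truth` (a `ground_truth`: per-cell disc membership plus the planted
#'   parameters).
#' @export
plant_clusters <- function(table, planted, config, seed = config$seed + 1L) {
  stopifnot(inherits(table, "cell_table"))
  if (length(planted) == 0L) {
    truth <- structure(list(
      planted = list(),
      membership = data.frame(cell_id = character(0), disc = integer(0),
                              stringsAsFactors = FALSE)),
      class = "ground_truth")
    return(list(cells = table, truth = truth))
  }
  stopifnot(all(vapply(planted, inherits, logical(1), "planted_cluster")))
  nd <- length(planted)
  if (nd > 1L) {
    for (i in seq_len(nd - 1L)) for (j in seq(i + 1L, nd)) {
      di <- planted[[i]]; dj <- planted[[j]]
      touch <- sum((di$center - dj$center)^2) < (di$radius + dj$radius)^2
      if (touch && di$class != dj$class) {
        stop("overlapping discs enrich opposite classes (discs ", i, ", ", j, ")")
      }
    }
  }
  df <- as.data.frame(table)
  with_seed(seed, {
    member <- rep(NA_integer_, nrow(df))
    for (k in seq_len(nd)) {
      disc <- planted[[k]]
      idx <- which(in_disc(df$x, df$y, disc))
      member[idx] <- k
      if (length(idx) > 0L) {
        enriched <- rbinom(length(idx), 1L, disc$fraction) == 1L
        other <- setdiff(CLASS_LEVELS, disc$class)
        df$class[idx] <- ifelse(enriched, disc$class, other)
        mix <- disc$subclass_mix
        if (is.null(mix)) mix <- config$subclass_mix
        df$subclass[idx] <- draw_subclasses(df$class[idx], mix)
      }
      if (disc$density_mult > 1) {
        rate <- (disc$density_mult - 1) * config$lambda *
          pi * disc$radius^2 / 1e6
        n_new <- rpois(1L, rate)
        if (n_new > 0L) {
          # rejection-free uniform draw in the disc
          r <- disc$radius * sqrt(runif(n_new))
          th <- runif(n_new, 0, 2 * pi)
          nx <- disc$center[1] + r * cos(th)
          ny <- disc$center[2] + r * sin(th)
          ncls <- ifelse(rbinom(n_new, 1L, disc$fraction) == 1L,
                         disc$class, setdiff(CLASS_LEVELS, disc$class))
          mix <- disc$subclass_mix
          if (is.null(mix)) mix <- config$subclass_mix
          nsub <- draw_subclasses(ncls, mix)
          extra <- data.frame(
            cell_id = sprintf("p%d_%06d", k, seq_len(n_new)),
            x = nx, y = ny, section_id = config$section_id,
            layer = scene_layer_of(config, ny),
            region = scene_region_of(config, nx),
            class = ncls, subclass = nsub, stringsAsFactors = FALSE)
          df <- rbind(df, extra)
          member <- c(member, rep(k, n_new))
        }
      }
    }
    out <- cell_table(df, subclass_vocab = lapply(config$subclass_mix, names))
    truth <- structure(list(
      planted = planted,
      membership = data.frame(cell_id = df$cell_id, disc = member,
                              stringsAsFactors = FALSE)),
      class = "ground_truth")
    list(cells = out, truth = truth)
  })
}

#' Cells planted inside a given disc
#'
#' @param truth a `ground_truth` from [plant_clusters()].
#' @param disc disc index.
#' @return Character vector of member `cell_id`s.
#' @export
truth_members <- function(truth, disc) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$membership$cell_id[!is.na(truth$membership$disc) &
                             truth$membership$disc == disc]
}

#' Generate a scene with an overlapping excitatory-inhibitory cluster pair
#'
#' Builds a background and enriches two discs - one excitatory, one
#' inhibitory - whose intersection is controlled by their centres and radius,
#' giving a known shared cell set for partnership tests. Cells in the
#' intersection are resampled with an intermediate inhibitory probability.
#'
#' @param config a [scene_config()].
#' @param overlap list with `center_e`, `center_i` (numeric length-2),
#'   `radius` (shared radius, um), and optionally `frac_e` (excitatory
#'   fraction in the E-only lune, default 0.95), `frac_i` (inhibitory
#'   fraction in the I-only lune, default 0.5) and `p_inh_both` (inhibitory
#'   probability in the intersection, default 0.5).
#' @param seed integer seed.
#' @return List with `cells` and `truth`; `truth$members_e`,
#'   `truth$members_i` and `truth$members_both` hold the disc and
#'   intersection memberships.
#' @export
generate_partner_scene <- function(config, overlap, seed = config$seed + 2L) {
  stopifnot(inherits(config, "scene_config"))
  frac_e <- if (is.null(overlap$frac_e)) 0.95 else overlap$frac_e
  frac_i <- if (is.null(overlap$frac_i)) 0.5 else overlap$frac_i
  p_both <- if (is.null(overlap$p_inh_both)) 0.5 else overlap$p_inh_both
  disc_e <- list(center = as.numeric(overlap$center_e), radius = overlap$radius)
  disc_i <- list(center = as.numeric(overlap$center_i), radius = overlap$radius)
  bg <- generate_background(config)
  df <- as.data.frame(bg)
  with_seed(seed, {
    in_e <- in_disc(df$x, df$y, disc_e)
    in_i <- in_disc(df$x, df$y, disc_i)
    both <- in_e & in_i
    only_e <- in_e & !both
    only_i <- in_i & !both
    p_i_of <- function(idx, p) rbinom(sum(idx), 1L, p) == 1L
    df$class[only_e] <- ifelse(p_i_of(only_e, 1 - frac_e), "inhibitory", "excitatory")
    df$class[only_i] <- ifelse(p_i_of(only_i, frac_i), "inhibitory", "excitatory")
    df$class[both]   <- ifelse(p_i_of(both, p_both), "inhibitory", "excitatory")
    touched <- in_e | in_i
    df$subclass[touched] <- draw_subclasses(df$class[touched], config$subclass_mix)
    cells <- cell_table(df, subclass_vocab = lapply(config$subclass_mix, names))
    truth <- structure(list(
      disc_e = disc_e, disc_i = disc_i,
      members_e = df$cell_id[in_e],
      members_i = df$cell_id[in_i],
      members_both = df$cell_id[both]),
      class = "partner_truth")
    list(cells = cells, truth = truth)
  })
}
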