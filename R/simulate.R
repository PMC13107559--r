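# Synthetic degron study generator. The genome is a single chromosome split
# into an active block - a slot architecture of convergent-CTCF loops that
# hosts the planted H3K27ac topology classes - and a structural block of
# large CTCF-only loops (the TAD-scale tier that dominates genomic coverage
# and hosts the gene models). Every placement is constructed so that the
# default classifier provably recovers the planted relation; counts follow
# a latent-rate scheme (log-normal strength x gamma dispersion shared
# across conditions, Poisson sampling per library) giving negative-binomial
# marginals while keeping the conditional binomial differential test exact.
# One integer seed determines every output.

.class_vocab <- c("contain_I", "contain_II", "contain_III",
                  "contain_and_cross", "cross", "neighbor", "inside",
                  "outside")

#' Simulation configuration
#'
#' Defaults encode the study's qualitative design: a class mix dominated by
#' contain and contain & cross (together just under 80%), cross and outside
#' under 10%; depletion weakening contain-III most, then contain-II, with
#' contain-I untouched; a strong-insulator subset of cross-type
#' strengthened on depletion; sharply localized accessibility losses at a
#' fraction of CTCF sites, rescued by both wild-type and loop-deficient
#' CTCF; and downregulated genes coupled to promoter CTCF binding with
#' mostly loop-independent rescue.
#'
#' @param seed integer master seed; fully determines all outputs.
#' @param genome named length-1 vector: one chromosome and its size in bp.
#' @param active_fraction fraction of the chromosome carrying the slot
#'   architecture; the remainder holds the structural loop tier.
#' @param n_ctcf_loops convergent-motif loops in the active block.
#' @param n_structural_loops,structural_loop_size the large-loop tier.
#' @param anchor_width,h3k_anchor_width anchor widths in bp.
#' @param n_h3k27ac planted regulatory interactions.
#' @param class_mix named proportions over
#'   `contain_I/II/III, contain_and_cross, cross, neighbor, inside,
#'   outside`; must sum to 1.
#' @param strength_lognormal `c(meanlog, sdlog)` of loop strength (strength
#'   is the expected contact count at unit depth).
#' @param depletion_effect named multiplicative IAA count effects per class.
#' @param cross_strong_quantile,cross_strong_effect cross-type interactions
#'   whose host CTCF loop strength reaches this quantile get this
#'   enhancement under depletion (insulation loss).
#' @param conditions interaction library conditions (first is baseline).
#' @param depth named per-condition depth factors for interaction counts.
#' @param dispersion latent-rate gamma dispersion for interaction/ATAC
#'   counts.
#' @param n_background_ctcf_sites CTCF peaks outside loop anchors.
#' @param n_background_motifs motif hits away from peaks.
#' @param atac_window,atac_n_background,atac_effect_fraction,
#'   atac_effect_size,atac_base_lognormal ATAC window generation: window
#'   width, background (non-CTCF) windows, fraction of CTCF windows losing
#'   accessibility, multiplicative IAA effect, base-rate log-normal.
#' @param n_genes,n_reps,deg_fraction,deg_down_fraction,deg_lfc,
#'   expr_base_lognormal,expr_dispersion expression design: gene count,
#'   replicates per condition, DEG fraction, fraction of DEGs that go down,
#'   planted |log2 fold change|, base-mean log-normal, replicate NB
#'   dispersion.
#' @param expr_conditions the four-condition degron design.
#' @param rescue_mix,up_rescue_mix rescue-class proportions among down- and
#'   up-regulated DEGs.
#' @param p_promoter_ctcf named probabilities of promoter CTCF binding per
#'   gene stratum (`loop_independent`, `loop_dependent`, `none`,
#'   `up`, `background`).
#' @param promoter_interaction_effect IAA effect of the EP/PP interactions
#'   planted at loop-dependent gene promoters.
#' @param motif_offset `c(mean, sd)` of motif-center placement relative to
#'   the TSS (negative = upstream).
#' @param n_nonlooping H3K27ac loci kept out of all interactions.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = c(chrS = 2e7),
                       active_fraction = 0.4,
                       n_ctcf_loops = 30,
                       n_structural_loops = 16,
                       structural_loop_size = 6.5e5,
                       anchor_width = 1000,
                       h3k_anchor_width = 1000,
                       n_h3k27ac = 1000,
                       class_mix = c(contain_I = 0.18, contain_II = 0.16,
                                     contain_III = 0.11,
                                     contain_and_cross = 0.33, cross = 0.05,
                                     neighbor = 0.08, inside = 0.05,
                                     outside = 0.04),
                       strength_lognormal = c(meanlog = 4, sdlog = 0.8),
                       depletion_effect = c(contain_I = 1, contain_II = 0.5,
                                            contain_III = 0.25,
                                            contain_and_cross = 1, cross = 1,
                                            neighbor = 1, inside = 1,
                                            outside = 1),
                       cross_strong_quantile = 0.7,
                       cross_strong_effect = 2,
                       conditions = c("untreated", "IAA"),
                       depth = c(untreated = 1, IAA = 1),
                       dispersion = 0.05,
                       n_background_ctcf_sites = 300,
                       n_background_motifs = 200,
                       atac_window = 300,
                       atac_n_background = 1000,
                       atac_effect_fraction = 0.4,
                       atac_group2_fraction = 0.1,
                       atac_effect_size = 0.3,
                       atac_base_lognormal = c(meanlog = 4, sdlog = 0.6),
                       n_genes = 2000,
                       n_reps = 3,
                       deg_fraction = 0.1,
                       deg_down_fraction = 0.8,
                       deg_lfc = 1.5,
                       expr_base_lognormal = c(meanlog = 5, sdlog = 1.5),
                       expr_dispersion = 0.05,
                       expr_conditions = c("untreated", "IAA", "wt_IAA",
                                           "mut_IAA"),
                       rescue_mix = c(loop_independent = 0.7,
                                      loop_dependent = 0.2, none = 0.1),
                       up_rescue_mix = c(loop_independent = 0.9,
                                         loop_dependent = 0, none = 0.1),
                       p_promoter_ctcf = c(loop_independent = 1,
                                           loop_dependent = 0.9, none = 0.5,
                                           up = 0.9, background = 0.25),
                       promoter_interaction_effect = 0.25,
                       motif_offset = c(mean = -57, sd = 5),
                       n_nonlooping = 400) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg `sim_config` list.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  if (length(cfg$genome) != 1 || is.null(names(cfg$genome)) ||
      cfg$genome <= 0)
    stop("genome must be one named chromosome with positive length")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  unknown <- setdiff(names(cfg$class_mix), .class_vocab)
  if (length(unknown))
    stop("unknown topology class in class_mix: ",
         paste(unknown, collapse = ", "))
  if (any(cfg$class_mix < 0)) stop("class_mix proportions must be >= 0")
  if (any(cfg$depletion_effect <= 0)) stop("depletion effects must be > 0")
  if (any(cfg$depth <= 0)) stop("depth factors must be > 0")
  if (cfg$dispersion < 0 || cfg$expr_dispersion < 0)
    stop("dispersion must be >= 0")
  if (abs(sum(cfg$rescue_mix) - 1) > 1e-9 ||
      abs(sum(cfg$up_rescue_mix) - 1) > 1e-9)
    stop("rescue mixes must sum to 1")
  if (cfg$n_reps < 2) stop("need >= 2 replicates per condition")
  if (cfg$active_fraction <= 0 || cfg$active_fraction >= 1)
    stop("active_fraction must be in (0, 1)")
  invisible(cfg)
}

.runi <- function(lo, hi) {
  if (hi < lo) stop("infeasible placement window")
  round(stats::runif(1, lo, hi))
}

# Latent-rate counts: one gamma-jittered rate per feature, Poisson per
# condition library.
.latent_counts <- function(strength, depth, effects, dispersion) {
  n <- length(strength)
  g <- if (dispersion > 0)
    stats::rgamma(n, shape = 1 / dispersion, scale = dispersion) else rep(1, n)
  rate <- strength * g
  out <- list()
  for (cond in names(depth)) {
    eff <- if (cond %in% colnames(effects)) effects[, cond] else rep(1, n)
    out[[cond]] <- stats::rpois(n, rate * depth[[cond]] * eff)
  }
  out
}

#' Simulate the CTCF loop architecture
#'
#' Active-block loops occupy the middle of evenly sized slots with jittered
#' anchors carrying convergent motifs (`+` left, `-` right); the structural
#' block carries large CTCF-only loops. Strengths are log-normal; contact
#' counts follow the latent-rate scheme at the configured depths.
#'
#' @param cfg [sim_config()].
#' @return list with `loops` (canonical loop table), `peaks`, `motifs`
#'   (stranded, scored), and the `slots` placement table used by
#'   [plant_h3k27ac_interactions()].
#' @export
simulate_ctcf_architecture <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  chrom <- names(cfg$genome)
  G <- unname(cfg$genome)
  A <- floor(G * cfg$active_fraction)
  w <- cfg$anchor_width
  n <- cfg$n_ctcf_loops
  if (n > 0) {
    L <- A / n
    if (L < 160e3)
      stop("infeasible loop density: n_ctcf_loops = ", n,
           " gives slots of ", round(L), " bp; need >= 160 kb")
  }
  slots <- NULL
  loops_list <- list()
  for (i in seq_len(n)) {
    slot0 <- floor((i - 1) * A / max(n, 1))
    L <- A / max(n, 1)
    s <- slot0 + round((0.35 + stats::runif(1, -0.02, 0.02)) * L)
    e <- slot0 + round((0.65 + stats::runif(1, -0.02, 0.02)) * L)
    loops_list[[i]] <- data.frame(
      id = paste0("ctcf_", i), chrom = chrom,
      start1 = s - w / 2, end1 = s + w / 2,
      start2 = e - w / 2, end2 = e + w / 2, stringsAsFactors = FALSE)
    slots <- rbind(slots, data.frame(
      loop_id = paste0("ctcf_", i), slot_start = slot0,
      slot_end = floor(slot0 + L), s = s, e = e, stringsAsFactors = FALSE))
  }
  ns <- cfg$n_structural_loops
  for (j in seq_len(ns)) {
    pitch <- (G - A) / ns
    span <- min(cfg$structural_loop_size, 0.9 * pitch)
    s <- A + round((j - 1) * pitch + (pitch - span) / 2)
    e <- s + round(span)
    loops_list[[n + j]] <- data.frame(
      id = paste0("ctcfS_", j), chrom = chrom,
      start1 = s - w / 2, end1 = s + w / 2,
      start2 = e - w / 2, end2 = e + w / 2, stringsAsFactors = FALSE)
  }
  loops <- if (length(loops_list)) do.call(rbind, loops_list) else
    data.frame(id = character(), chrom = character(), start1 = numeric(),
               end1 = numeric(), start2 = numeric(), end2 = numeric(),
               stringsAsFactors = FALSE)
  nl <- nrow(loops)
  loops$strength <- if (nl) stats::rlnorm(nl, cfg$strength_lognormal[["meanlog"]],
                                          cfg$strength_lognormal[["sdlog"]]) else numeric(0)
  cnt <- .latent_counts(loops$strength, cfg$depth,
                        matrix(1, nl, 0), cfg$dispersion)
  for (cond in names(cfg$depth)) loops[[paste0("count_", cond)]] <- cnt[[cond]]
  loops <- canonicalize_loops(loops)

  anchors <- loop_anchors(loops)
  mids <- interval_midpoints(anchors)
  na <- nrow(anchors)
  peaks <- data.frame(chrom = rep(chrom, na), start = pmax(0, mids - 200),
                      end = mids + 200,
                      name = if (na) paste0("peak_", anchors$id, "_",
                                            anchors$side) else character(0),
                      score = rep(loops$strength, 2),
                      stringsAsFactors = FALSE)
  motifs <- data.frame(chrom = rep(chrom, na), start = mids - 9,
                       end = mids + 10,
                       name = if (na) paste0("motif_", anchors$id, "_",
                                             anchors$side) else character(0),
                       score = round(stats::runif(na, 10, 25), 2),
                       strand = ifelse(anchors$side == "L", "+", "-"),
                       stringsAsFactors = FALSE)
  # background CTCF sites (peaks without loops) and weak background motifs
  if (cfg$n_background_ctcf_sites > 0) {
    pos <- sort(round(stats::runif(cfg$n_background_ctcf_sites, 1000, G - 1000)))
    peaks <- rbind(peaks, data.frame(
      chrom = chrom, start = pos - 200, end = pos + 200,
      name = paste0("peak_bg_", seq_along(pos)),
      score = stats::rlnorm(length(pos), cfg$strength_lognormal[["meanlog"]] - 1,
                            cfg$strength_lognormal[["sdlog"]]),
      stringsAsFactors = FALSE))
    motifs <- rbind(motifs, data.frame(
      chrom = chrom, start = pos - 9, end = pos + 10,
      name = paste0("motif_bg_", seq_along(pos)),
      score = round(stats::runif(length(pos), 4, 12), 2),
      strand = sample(c("+", "-"), length(pos), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  if (cfg$n_background_motifs > 0) {
    pos <- sort(round(stats::runif(cfg$n_background_motifs, 1000, G - 1000)))
    motifs <- rbind(motifs, data.frame(
      chrom = chrom, start = pos - 9, end = pos + 10,
      name = paste0("motif_free_", seq_along(pos)),
      score = round(stats::runif(length(pos), 2, 8), 2),
      strand = sample(c("+", "-"), length(pos), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  list(loops = loops, peaks = peaks, motifs = motifs, slots = slots)
}

# Geometric placement of one interaction of the requested class relative to
# its host slot(s). Returns midpoints c(m1, m2) plus optional exact shared
# anchors, encoded as a list.
.place_interaction <- function(class, slot, next_slot, hw, w, max_off = 40e3) {
  s <- slot$s; e <- slot$e
  lo_left <- max(slot$slot_start + 0.02 * (slot$slot_end - slot$slot_start) + hw,
                 s - max_off)
  hi_left <- s - 3e3
  lo_right <- e + 3e3
  hi_right <- min(slot$slot_end - 0.02 * (slot$slot_end - slot$slot_start) - hw,
                  e + max_off)
  mid <- floor((s + e) / 2)
  share <- c(NA, NA)  # per side: "L"/"R" of host anchors shared exactly
  if (class == "contain_I") {
    m <- c(.runi(lo_left, hi_left), .runi(lo_right, hi_right))
  } else if (class == "contain_II") {
    if (stats::runif(1) < 0.5) {
      m <- c(s, .runi(lo_right, hi_right)); share[1] <- "L"
    } else {
      m <- c(.runi(lo_left, hi_left), e); share[2] <- "R"
    }
  } else if (class == "contain_III") {
    m <- c(s, e); share <- c("L", "R")
  } else if (class == "cross") {
    if (stats::runif(1) < 0.5) {
      m <- c(.runi(s + 4e3, mid - 2e3), .runi(lo_right, hi_right))
    } else {
      m <- c(.runi(lo_left, hi_left), .runi(mid + 2e3, e - 4e3))
    }
  } else if (class == "inside") {
    m <- c(.runi(s + 4e3, mid - 8e3), .runi(mid + 8e3, e - 4e3))
  } else if (class == "neighbor") {
    if (stats::runif(1) < 0.5) {
      m <- c(.runi(lo_left, s - 12e3), s); share[2] <- "L"
    } else {
      m <- c(e, .runi(e + 12e3, hi_right)); share[1] <- "R"
    }
  } else if (class == "outside") {
    m1 <- .runi(lo_left, hi_left - 12e3)
    m <- c(m1, .runi(m1 + 12e3, hi_left))
  } else if (class == "contain_and_cross") {
    s2 <- next_slot$s; e2 <- next_slot$e
    mid2 <- floor((s2 + e2) / 2)
    m <- c(.runi(lo_left, hi_left), .runi(s2 + 4e3, mid2 - 2e3))
  } else stop("unknown class: ", class)
  list(m = m, share = share)
}

#' Plant H3K27ac interactions with known topology classes
#'
#' Each interaction is geometrically constructed so that the default
#' classifier (slack 0, midpoint spans) provably assigns the planted
#' relation to its host CTCF loop and no relation to any other. IAA counts
#' are scaled by the class's depletion effect; cross-type interactions on
#' hosts at or above the strong-insulator strength quantile are enhanced
#' instead.
#'
#' @param cfg [sim_config()].
#' @param arch [simulate_ctcf_architecture()] output.
#' @return list with `interactions` (canonical loop table) and `truth`
#'   (per-interaction planted class, category, subtype, hosts, effect,
#'   `unambiguous` flag).
#' @export
plant_h3k27ac_interactions <- function(cfg, arch) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  chrom <- names(cfg$genome)
  G <- unname(cfg$genome)
  slots <- arch$slots
  n_active <- if (is.null(slots)) 0L else nrow(slots)
  mix <- cfg$class_mix
  nonoutside <- setdiff(names(mix)[mix > 0], "outside")
  if (n_active == 0 && length(nonoutside))
    stop("classes ", paste(nonoutside, collapse = ", "),
         " need CTCF loops; n_ctcf_loops is 0")
  if (any(mix[names(mix) == "contain_and_cross"] > 0) && n_active < 2)
    stop("contain_and_cross needs >= 2 active CTCF loops")
  n <- cfg$n_h3k27ac
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  hw <- cfg$h3k_anchor_width
  w <- cfg$anchor_width
  active_strength <- if (n_active)
    arch$loops$strength[match(slots$loop_id, arch$loops$id)] else numeric(0)
  strong_cut <- if (length(active_strength))
    stats::quantile(active_strength, cfg$cross_strong_quantile, names = FALSE)
  else Inf
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (n_active) {
      j <- if (cls == "contain_and_cross")
        sample.int(n_active - 1L, 1L) else sample.int(n_active, 1L)
      slot <- slots[j, ]
      next_slot <- if (j < n_active) slots[j + 1, ] else NULL
    } else {
      # outside-only world: place anywhere in the active block
      j <- NA_integer_
      pos <- .runi(5e3, floor(G * cfg$active_fraction) - 1e5)
      slot <- data.frame(slot_start = pos, slot_end = pos + 9e4,
                         s = pos + 5.5e4, e = pos + 8.5e4)
      next_slot <- NULL
    }
    pl <- .place_interaction(cls, slot, next_slot, hw, w)
    host <- if (!is.na(j)) slots$loop_id[j] else NA_character_
    host_strength <- if (!is.na(j)) active_strength[j] else NA_real_
    cross_host <- if (cls == "contain_and_cross") slots$loop_id[j + 1]
    else if (cls == "cross") host else NA_character_
    cross_strength <- if (cls == "contain_and_cross") active_strength[j + 1]
    else if (cls == "cross") host_strength else NA_real_
    eff <- unname(cfg$depletion_effect[[if (cls %in% c("contain_I", "contain_II",
                                                       "contain_III"))
      cls else cls]])
    if (cls == "cross" && !is.na(cross_strength) &&
        cross_strength >= strong_cut)
      eff <- cfg$cross_strong_effect
    # anchors: exact host-anchor copies where the construction shares them
    a1 <- if (identical(pl$share[1], "L")) c(slot$s - w / 2, slot$s + w / 2)
    else if (identical(pl$share[1], "R")) c(slot$e - w / 2, slot$e + w / 2)
    else c(pl$m[1] - hw / 2, pl$m[1] + hw / 2)
    a2 <- if (identical(pl$share[2], "L")) c(slot$s - w / 2, slot$s + w / 2)
    else if (identical(pl$share[2], "R")) c(slot$e - w / 2, slot$e + w / 2)
    else c(pl$m[2] - hw / 2, pl$m[2] + hw / 2)
    rows[[i]] <- data.frame(
      id = paste0("h3k_", i), chrom = chrom,
      start1 = a1[1], end1 = a1[2], start2 = a2[1], end2 = a2[2],
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      id = paste0("h3k_", i), class = cls,
      category = if (cls %in% c("contain_I", "contain_II", "contain_III"))
        "contain" else cls,
      contain_subtype = switch(cls, contain_I = 1L, contain_II = 2L,
                               contain_III = 3L,
                               contain_and_cross = 1L, NA_integer_),
      host_id = host, host_strength = host_strength,
      cross_host_id = cross_host, cross_host_strength = cross_strength,
      effect = eff, unambiguous = TRUE, stringsAsFactors = FALSE)
  }
  interactions <- canonicalize_loops(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  interactions$strength <- stats::rlnorm(
    n, cfg$strength_lognormal[["meanlog"]], cfg$strength_lognormal[["sdlog"]])
  effects <- matrix(1, n, 1, dimnames = list(NULL, "IAA"))
  effects[, "IAA"] <- truth$effect
  cnt <- .latent_counts(interactions$strength, cfg$depth, effects,
                        cfg$dispersion)
  for (cond in names(cfg$depth))
    interactions[[paste0("count_", cond)]] <- cnt[[cond]]
  list(interactions = interactions, truth = truth)
}

#' Simulate ATAC window counts around CTCF sites
#'
#' Fixed-width windows centered on every CTCF peak plus background windows;
#' a configured fraction of CTCF windows loses accessibility under IAA by
#' the configured multiplicative effect, and both rescue conditions restore
#' it. Counts follow the latent-rate scheme.
#'
#' @param cfg [sim_config()].
#' @param ctcf_peaks interval table of CTCF sites.
#' @param ctcf_motifs optional motif table; motif hits away from any peak
#'   become "Group 2" windows - sub-threshold CTCF sites that can still
#'   lose accessibility without carrying a called peak.
#' @return list with `windows` (feature table with `id` and
#'   `count_<condition>` columns over the four-condition design) and
#'   `truth` (`id`, `is_ctcf`, `has_motif`, `affected`).
#' @export
simulate_atac <- function(cfg, ctcf_peaks, ctcf_motifs = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  chrom <- names(cfg$genome)
  G <- unname(cfg$genome)
  wins <- ctcf_centered_windows(ctcf_peaks, width = cfg$atac_window,
                                chrom_sizes = cfg$genome)
  wins$id <- paste0("win_ctcf_", seq_len(nrow(wins)))
  wins <- wins[c("chrom", "start", "end", "name", "id")]
  is_ctcf <- rep(TRUE, nrow(wins))
  has_motif <- rep(TRUE, nrow(wins))
  if (!is.null(ctcf_motifs) && nrow(ctcf_motifs)) {
    solo <- ctcf_motifs[!overlaps_any(ctcf_motifs, ctcf_peaks), ,
                        drop = FALSE]
    if (nrow(solo)) {
      mw <- ctcf_centered_windows(solo, width = cfg$atac_window,
                                  chrom_sizes = cfg$genome)
      mw$id <- paste0("win_motif_", seq_len(nrow(mw)))
      wins <- rbind(wins, mw[c("chrom", "start", "end", "name", "id")])
      is_ctcf <- c(is_ctcf, rep(FALSE, nrow(mw)))
      has_motif <- c(has_motif, rep(TRUE, nrow(mw)))
    }
  }
  n_motif_only <- sum(!is_ctcf)
  if (cfg$atac_n_background > 0) {
    pos <- sort(round(stats::runif(cfg$atac_n_background, 1000, G - 1000)))
    bg <- data.frame(chrom = chrom, start = pos - cfg$atac_window / 2,
                     end = pos + cfg$atac_window / 2,
                     name = paste0("bg_", seq_along(pos)),
                     id = paste0("win_bg_", seq_along(pos)),
                     stringsAsFactors = FALSE)
    wins <- rbind(wins, bg)
    is_ctcf <- c(is_ctcf, rep(FALSE, nrow(bg)))
    has_motif <- c(has_motif, rep(FALSE, nrow(bg)))
  }
  n <- nrow(wins)
  affected <- rep(FALSE, n)
  idx_peak <- which(is_ctcf)
  n_aff <- round(cfg$atac_effect_fraction * length(idx_peak))
  if (n_aff > 0)
    affected[sample(idx_peak, n_aff)] <- TRUE
  idx_solo <- which(!is_ctcf & has_motif)
  n_aff2 <- min(length(idx_solo),
                round(n_aff * cfg$atac_group2_fraction /
                        (1 - cfg$atac_group2_fraction)))
  if (n_aff2 > 0)
    affected[sample(idx_solo, n_aff2)] <- TRUE
  base <- stats::rlnorm(n, cfg$atac_base_lognormal[["meanlog"]],
                        cfg$atac_base_lognormal[["sdlog"]])
  effects <- matrix(1, n, 1, dimnames = list(NULL, "IAA"))
  effects[affected, "IAA"] <- cfg$atac_effect_size
  depth <- stats::setNames(rep(1, length(cfg$expr_conditions)),
                           cfg$expr_conditions)
  cnt <- .latent_counts(base, depth, effects, cfg$dispersion)
  for (cond in names(depth)) wins[[paste0("count_", cond)]] <- cnt[[cond]]
  truth <- data.frame(id = wins$id, is_ctcf = is_ctcf,
                      has_motif = has_motif, affected = affected,
                      stringsAsFactors = FALSE)
  list(windows = wins, truth = truth)
}

#' Simulate gene expression across the four-condition degron design
#'
#' DEGs go down (or up) under IAA; loop-independent genes return to
#' baseline under both rescue constructs, loop-dependent genes only under
#' wild-type CTCF, and `none` genes stay deregulated in every IAA-treated
#' condition (the globally IAA-responsive stratum). Promoter CTCF binding
#' probabilities are stratum-specific. Counts are negative-binomial per
#' replicate.
#'
#' @param cfg [sim_config()].
#' @param gene_models optional pre-built gene table (`gene_id`, `chrom`,
#'   `tss`, `strand`); generated in the structural block by default.
#' @return list with `gene_models`, `counts` (genes x samples), `design`,
#'   and `truth` (`gene_id`, `deg`, `direction`, `rescue_class`,
#'   `promoter_ctcf`, `base_mean`).
#' @export
simulate_expression <- function(cfg, gene_models = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 4L)
  chrom <- names(cfg$genome)
  G <- unname(cfg$genome)
  A <- floor(G * cfg$active_fraction)
  ng <- cfg$n_genes
  if (is.null(gene_models)) {
    tss <- sort(round(stats::runif(ng, A + 1e5, G - 1e5)))
    gene_models <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(ng)), chrom = chrom, tss = tss,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ng <- nrow(gene_models)
  deg <- stats::runif(ng) < cfg$deg_fraction
  direction <- rep("unchanged", ng)
  direction[deg] <- ifelse(stats::runif(sum(deg)) < cfg$deg_down_fraction,
                           "down", "up")
  rescue <- rep(NA_character_, ng)
  idx_down <- which(direction == "down")
  rescue[idx_down] <- sample(names(cfg$rescue_mix), length(idx_down),
                             replace = TRUE, prob = cfg$rescue_mix)
  idx_up <- which(direction == "up")
  rescue[idx_up] <- sample(names(cfg$up_rescue_mix), length(idx_up),
                           replace = TRUE, prob = cfg$up_rescue_mix)
  stratum <- ifelse(!deg, "background",
                    ifelse(direction == "up", "up", rescue))
  p_ctcf <- cfg$p_promoter_ctcf[stratum]
  promoter_ctcf <- stats::runif(ng) < p_ctcf
  base <- stats::rlnorm(ng, cfg$expr_base_lognormal[["meanlog"]],
                        cfg$expr_base_lognormal[["sdlog"]])
  fold <- ifelse(direction == "down", 2^(-cfg$deg_lfc),
                 ifelse(direction == "up", 2^cfg$deg_lfc, 1))
  mu <- matrix(base, ng, 4,
               dimnames = list(gene_models$gene_id, cfg$expr_conditions))
  mu[, "IAA"] <- base * fold
  mu[, "wt_IAA"] <- ifelse(deg & rescue == "none" & !is.na(rescue),
                           base * fold, base)
  mu[, "mut_IAA"] <- ifelse(deg & !is.na(rescue) &
                              rescue %in% c("loop_dependent", "none"),
                            base * fold, base)
  samples <- as.vector(t(outer(cfg$expr_conditions,
                               seq_len(cfg$n_reps),
                               function(c, r) paste0(c, "_rep", r))))
  design <- data.frame(sample = samples,
                       condition = rep(cfg$expr_conditions,
                                       each = cfg$n_reps),
                       stringsAsFactors = FALSE)
  counts <- matrix(0L, ng, length(samples),
                   dimnames = list(gene_models$gene_id, samples))
  for (k in seq_along(samples)) {
    m <- mu[, design$condition[k]]
    counts[, k] <- if (cfg$expr_dispersion > 0)
      stats::rnbinom(ng, mu = m, size = 1 / cfg$expr_dispersion)
    else stats::rpois(ng, m)
  }
  truth <- data.frame(gene_id = gene_models$gene_id, deg = deg,
                      direction = direction, rescue_class = rescue,
                      promoter_ctcf = promoter_ctcf, base_mean = base,
                      stringsAsFactors = FALSE)
  list(gene_models = gene_models, counts = counts, design = design,
       truth = truth)
}

#' Simulate a complete synthetic degron study
#'
#' Couples the architecture, interaction, accessibility and expression
#' generators: promoter CTCF peaks and motifs (centered near the configured
#' upstream offset) are placed for flagged genes; every loop-dependent
#' downregulated gene receives an EP interaction at its promoter that loses
#' contacts under IAA; H3K27ac loci are emitted for all interaction anchors
#' plus isolated non-looping sites; ATAC windows cover the full CTCF site
#' set.
#'
#' @param cfg [sim_config()].
#' @param outdir optional directory; when given, all study files are
#'   written (BEDPE/BED/TSV/JSON) and the paths returned in the result.
#' @return list with `config`, `ctcf` (loops/peaks/motifs), `interactions`,
#'   `enhancers`, `h3k_sites`, `atac`, `expression`, `gene_models`, and
#'   `truth` (interactions, atac, genes, h3k_sites).
#' @export
simulate_study <- function(cfg, outdir = NULL) {
  validate_sim_config(cfg)
  chrom <- names(cfg$genome)
  arch <- simulate_ctcf_architecture(cfg)
  planted <- plant_h3k27ac_interactions(cfg, arch)
  expr <- simulate_expression(cfg)
  set.seed(cfg$seed + 5L)
  gm <- expr$gene_models
  truth_genes <- expr$truth

  # promoter CTCF peaks + motifs near the configured TSS offset
  flagged <- which(truth_genes$promoter_ctcf)
  sgn <- ifelse(gm$strand[flagged] == "+", 1, -1)
  off <- round(stats::rnorm(length(flagged), cfg$motif_offset[["mean"]],
                            cfg$motif_offset[["sd"]]))
  center <- gm$tss[flagged] + sgn * off
  prom_peaks <- data.frame(chrom = chrom, start = pmax(0, center - 200),
                           end = center + 200,
                           name = paste0("peak_prom_", gm$gene_id[flagged]),
                           score = stats::rlnorm(length(flagged),
                                                 cfg$strength_lognormal[["meanlog"]],
                                                 cfg$strength_lognormal[["sdlog"]]),
                           stringsAsFactors = FALSE)
  prom_motifs <- data.frame(chrom = chrom, start = center - 9,
                            end = center + 10,
                            name = paste0("motif_prom_", gm$gene_id[flagged]),
                            score = round(stats::runif(length(flagged), 10, 25), 2),
                            strand = gm$strand[flagged],
                            stringsAsFactors = FALSE)
  peaks <- rbind(arch$peaks, prom_peaks)
  motifs <- rbind(arch$motifs[c("chrom", "start", "end", "name", "score",
                                "strand")], prom_motifs)

  # EP interactions at loop-dependent downregulated gene promoters
  ld <- which(truth_genes$direction == "down" &
                truth_genes$rescue_class == "loop_dependent")
  hw <- cfg$h3k_anchor_width
  prom_inter <- NULL
  enh_rows <- NULL
  if (length(ld)) {
    dir <- sample(c(-1, 1), length(ld), replace = TRUE)
    dist <- round(stats::runif(length(ld), 3e4, 8e4))
    other <- gm$tss[ld] + dir * dist
    other <- pmin(pmax(other, 5e3), unname(cfg$genome) - 5e3)
    strength <- stats::rlnorm(length(ld), 5, 0.3)
    prom_inter <- data.frame(
      id = paste0("h3kP_", gm$gene_id[ld]), chrom = chrom,
      start1 = gm$tss[ld] - hw / 2, end1 = gm$tss[ld] + hw / 2,
      start2 = other - hw / 2, end2 = other + hw / 2,
      strength = strength, stringsAsFactors = FALSE)
    prom_inter <- canonicalize_loops(prom_inter)
    effects <- matrix(cfg$promoter_interaction_effect, length(ld), 1,
                      dimnames = list(NULL, "IAA"))
    cnt <- .latent_counts(strength, cfg$depth, effects, cfg$dispersion)
    for (cond in names(cfg$depth))
      prom_inter[[paste0("count_", cond)]] <- cnt[[cond]]
    enh_rows <- data.frame(chrom = chrom, start = other - 500,
                           end = other + 500,
                           name = paste0("enh_", gm$gene_id[ld]),
                           stringsAsFactors = FALSE)
  }
  interactions <- rbind(planted$interactions, prom_inter)
  truth_inter <- planted$truth
  if (length(ld)) {
    truth_inter <- rbind(truth_inter, data.frame(
      id = paste0("h3kP_", gm$gene_id[ld]), class = NA_character_,
      category = NA_character_, contain_subtype = NA_integer_,
      host_id = NA_character_, host_strength = NA_real_,
      cross_host_id = NA_character_, cross_host_strength = NA_real_,
      effect = cfg$promoter_interaction_effect, unambiguous = FALSE,
      stringsAsFactors = FALSE))
    truth_inter$gene_id <- c(rep(NA_character_, nrow(planted$truth)),
                             gm$gene_id[ld])
  } else truth_inter$gene_id <- NA_character_

  # enhancer annotation: planted EP anchors plus a sample of geometric
  # interaction anchors and random background elements
  anchors <- loop_anchors(planted$interactions)
  pick <- sample(nrow(anchors), round(0.4 * nrow(anchors)))
  enh <- rbind(
    enh_rows,
    data.frame(chrom = anchors$chrom[pick], start = anchors$start[pick],
               end = anchors$end[pick],
               name = paste0("enh_a_", seq_along(pick)),
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom,
               start = (p <- sort(round(stats::runif(100, 1e3,
                                                     unname(cfg$genome) - 1e3)))) - 500,
               end = p + 500, name = paste0("enh_bg_", seq_along(p)),
               stringsAsFactors = FALSE))
  rownames(enh) <- NULL

  # H3K27ac loci: all interaction anchors (looping) + isolated sites
  all_anchors <- loop_anchors(interactions)
  loci <- data.frame(chrom = all_anchors$chrom, start = all_anchors$start,
                     end = all_anchors$end,
                     name = paste0("k27_", all_anchors$id, "_",
                                   all_anchors$side),
                     stringsAsFactors = FALSE)
  looping_flag <- rep(TRUE, nrow(loci))
  if (cfg$n_nonlooping > 0) {
    G <- unname(cfg$genome)
    placed <- 0; tries <- 0
    pos <- numeric(0)
    while (placed < cfg$n_nonlooping && tries < 50 * cfg$n_nonlooping) {
      tries <- tries + 1
      cand <- round(stats::runif(1, 1e3, G - 1e3))
      probe <- data.frame(chrom = chrom, start = cand - 500, end = cand + 500,
                          stringsAsFactors = FALSE)
      if (!overlaps_any(probe, all_anchors, slack = 20e3)) {
        pos <- c(pos, cand); placed <- placed + 1
      }
    }
    loci <- rbind(loci, data.frame(
      chrom = chrom, start = pos - 500, end = pos + 500,
      name = paste0("k27_solo_", seq_along(pos)), stringsAsFactors = FALSE))
    looping_flag <- c(looping_flag, rep(FALSE, length(pos)))
  }
  truth_sites <- data.frame(name = loci$name, looping = looping_flag,
                            stringsAsFactors = FALSE)

  atac <- simulate_atac(cfg, peaks, motifs)

  study <- list(config = cfg,
                ctcf = list(loops = arch$loops, peaks = peaks,
                            motifs = motifs, slots = arch$slots),
                interactions = interactions, enhancers = enh,
                h3k_sites = loci, atac = atac$windows,
                expression = list(counts = expr$counts,
                                  design = expr$design),
                gene_models = gm,
                truth = list(interactions = truth_inter, atac = atac$truth,
                             genes = truth_genes, h3k_sites = truth_sites))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_bedpe(arch$loops, p("ctcf_loops.bedpe"), "ctcf_loops")
    write_bedpe(interactions, p("h3k27ac_interactions.bedpe"),
                "h3k27ac_interactions")
    write_bed(peaks, p("ctcf_peaks.bed"), "ctcf_peaks")
    write_bed(motifs, p("ctcf_motifs.bed"), "ctcf_motifs")
    write_bed(loci, p("h3k27ac_sites.bed"), "h3k27ac_sites")
    write_bed(enh, p("enhancers.bed"), "enhancers")
    write_tsv(atac$windows, p("atac_windows.tsv"), "atac_windows")
    counts_df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                            check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(counts_df, p("expression_counts.tsv"), "expression_counts")
    write_tsv(expr$design, p("expression_design.tsv"), "expression_design")
    write_tsv(gm, p("gene_models.tsv"), "gene_models")
    jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    cfg_out <- cfg
    class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, p("simconfig.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    study$files <- list.files(outdir, full.names = TRUE)
  }
  study
}
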