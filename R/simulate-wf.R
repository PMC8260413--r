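#' Specification for the forward Wright-Fisher simulator
#'
#' A discrete-generation diploid Wright-Fisher simulation with recombination
#' and infinite-sites mutation on an integer coordinate grid: one ancestral
#' population is burnt in, splits three ways, and the lineages then evolve
#' independently. One lineage may pass through a bottleneck (reduced diploid
#' size for the final generations), and one lineage may carry an additive
#' sweep (fitnesses 1, 1+hs, 1+s at the selected site). Output haplotypes are
#' phased. This simulator is the one that carries linkage, so it backs the
#' LD-decay and sweep-shape tests; the Balding-Nichols generator covers
#' everything that does not need linkage.
#'
#' Defaults are chosen for testability (the source study publishes no
#' demographic parameters): a small population with a high per-bp mutation
#' rate gives equilibrium diversity and tens-of-kb LD decay on a 300 kb
#' segment within seconds.
#'
#' @param N_e diploid population size per lineage.
#' @param L simulated sequence length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @param split_gens generations since the three-way split.
#' @param burnin_gens ancestral burn-in generations (default `10 * N_e`).
#' @param bottleneck `NULL` or `list(pop =, N =, duration =)`: the named
#'   lineage runs at diploid size `N < N_e` for its final `duration`
#'   generations.
#' @param sweep `NULL` or `list(pop =, pos =, s =, h =)`: a new beneficial
#'   allele is introduced as a single copy in the named lineage immediately
#'   after the split, at position `pos` (1..L), with selection coefficient `s`
#'   and dominance `h` (default 0.5).
#' @param loss_action `"resample"` (default) re-runs the selected lineage with
#'   fresh randomness when the beneficial allele is lost, up to
#'   `max_attempts`; `"fail"` stops instead.
#' @param max_attempts cap on sweep resampling attempts.
#' @param chrom_name chromosome label of the emitted sites.
#' @param seed integer RNG seed; the simulation is deterministic given it.
#' @return a list of class `WrightFisherSpec`.
#' @export
wf_spec <- function(N_e = 70, L = 300000L, mu = 2e-6, rho = 6e-7,
                    split_gens = 60L, burnin_gens = NULL,
                    bottleneck = NULL, sweep = NULL,
                    loss_action = c("resample", "fail"), max_attempts = 100L,
                    chrom_name = "chr1", seed = 1L) {
  loss_action <- match.arg(loss_action)
  if (is.null(burnin_gens)) burnin_gens <- 10L * N_e
  if (mu < 0 || rho < 0) stop("mutation and recombination rates must be >= 0")
  if (N_e < 2) stop("N_e must be >= 2")
  if (!is.null(bottleneck)) {
    stopifnot(all(c("pop", "N", "duration") %in% names(bottleneck)))
    if (!bottleneck$pop %in% POP_ROLES) stop("unknown bottleneck population")
    if (bottleneck$N >= N_e) stop("bottleneck size must be smaller than N_e")
    if (bottleneck$N < 2) stop("bottleneck size must be >= 2")
    if (bottleneck$duration > split_gens)
      stop("bottleneck duration cannot exceed split_gens")
  }
  if (!is.null(sweep)) {
    stopifnot(all(c("pop", "pos", "s") %in% names(sweep)))
    if (is.null(sweep$h)) sweep$h <- 0.5
    if (!sweep$pop %in% POP_ROLES) stop("unknown sweep population")
    if (sweep$pos < 1 || sweep$pos > L) stop("sweep position outside [1, L]")
  }
  # guard against runaway segregating-site counts (discrete-site capacity)
  exp_S <- 4 * N_e * mu * L * (log(2 * N_e) + 0.577)
  if (exp_S > 10 * L) stop("expected segregating sites exceed capacity; lower mu or L")
  structure(list(N_e = as.integer(N_e), L = as.integer(L), mu = mu, rho = rho,
                 split_gens = as.integer(split_gens),
                 burnin_gens = as.integer(burnin_gens),
                 bottleneck = bottleneck, sweep = sweep,
                 loss_action = loss_action, max_attempts = as.integer(max_attempts),
                 chrom_name = chrom_name, seed = as.integer(seed)),
            class = "WrightFisherSpec")
}

# one Wright-Fisher generation: N_next diploid offspring from the current
# haplotype pool H (rows = haplotypes, cols = segregating sites at `pos`),
# with optional parental fitnesses `fit` (one per diploid)
wf_generation <- function(H, pos, N_next, mu, rho, L, fit = NULL) {
  n_cur <- nrow(H) %/% 2L
  k2 <- 2L * N_next
  par <- sample.int(n_cur, k2, replace = TRUE, prob = fit)
  starth <- sample.int(2L, k2, replace = TRUE)
  ncx <- stats::rpois(k2, rho * L)
  Hn <- H[2L * (par - 1L) + starth, , drop = FALSE]
  for (k in which(ncx > 0L)) {
    cx <- sort(stats::runif(ncx[k], 0, L))
    swap <- (findInterval(pos, cx) %% 2L) == 1L
    if (any(swap)) {
      other <- 2L * (par[k] - 1L) + (3L - starth[k])
      Hn[k, swap] <- H[other, swap]
    }
  }
  nm <- stats::rpois(1L, k2 * mu * L)
  if (nm > 0L) {
    newpos <- sample.int(L, min(nm, L))
    newpos <- newpos[!(newpos %in% pos)]
    if (length(newpos)) {
      M <- matrix(0L, nrow = k2, ncol = length(newpos))
      M[cbind(sample.int(k2, length(newpos), replace = TRUE),
              seq_along(newpos))] <- 1L
      Hn <- cbind(Hn, M)
      pos <- c(pos, newpos)
    }
  }
  list(H = Hn, pos = pos)
}

# drop lost (and optionally fixed) columns; positions in `keep_pos` survive
wf_prune <- function(H, pos, drop_fixed = TRUE, keep_pos = integer(0)) {
  if (!length(pos)) return(list(H = H, pos = pos))
  cs <- colSums(H)
  keep <- cs > 0L
  if (drop_fixed) keep <- keep & cs < nrow(H)
  if (length(keep_pos)) keep <- keep | pos %in% keep_pos
  list(H = H[, keep, drop = FALSE], pos = pos[keep])
}

# evolve one post-split lineage for `gens` generations with a per-generation
# diploid-size schedule and optional selection at a tracked position
wf_evolve_lineage <- function(H, pos, N_sched, mu, rho, L, sel = NULL) {
  for (g in seq_along(N_sched)) {
    fit <- NULL
    if (!is.null(sel)) {
      idx <- match(sel$pos, pos)
      if (is.na(idx) || sum(H[, idx]) == 0L)
        return(list(H = H, pos = pos, lost = TRUE))
      gt <- H[seq(1L, nrow(H), by = 2L), idx] + H[seq(2L, nrow(H), by = 2L), idx]
      fit <- 1 + sel$h * sel$s * (gt == 1L) + sel$s * (gt == 2L)
    }
    st <- wf_generation(H, pos, N_sched[g], mu, rho, L, fit = fit)
    H <- st$H; pos <- st$pos
    if (g %% 5L == 0L || g == length(N_sched)) {
      st <- wf_prune(H, pos, drop_fixed = FALSE,
                     keep_pos = if (is.null(sel)) integer(0) else sel$pos)
      H <- st$H; pos <- st$pos
    }
  }
  lost <- FALSE
  if (!is.null(sel)) {
    idx <- match(sel$pos, pos)
    lost <- is.na(idx) || sum(H[, idx]) == 0L
  }
  list(H = H, pos = pos, lost = lost)
}

#' Simulate three diverged populations by forward Wright-Fisher dynamics
#'
#' See [wf_spec()] for the model. All `N` diploids of each lineage's final
#' generation are emitted as phased samples. Sites monomorphic across the
#' whole combined sample are dropped; fixed differences between populations
#' are retained.
#'
#' @param spec a [wf_spec()].
#' @return list with `gm` (phased `GenotypeMatrix`) and `truth` (`SimTruth`
#'   with the spec, realized per-population frequencies, sweep fate and the
#'   sweep's window ids on the standard 50 kb / 25 kb grid).
#' @export
simulate_wright_fisher <- function(spec) {
  stopifnot(inherits(spec, "WrightFisherSpec"))
  with_seed(spec$seed, {
    N <- spec$N_e; L <- spec$L
    H <- matrix(0L, nrow = 2L * N, ncol = 0L)
    pos <- integer(0)
    for (g in seq_len(spec$burnin_gens)) {
      st <- wf_generation(H, pos, N, spec$mu, spec$rho, L)
      H <- st$H; pos <- st$pos
      st <- wf_prune(H, pos, drop_fixed = TRUE)
      H <- st$H; pos <- st$pos
    }
    split_H <- H; split_pos <- pos

    sched <- function(p) {
      s <- rep(N, spec$split_gens)
      b <- spec$bottleneck
      if (!is.null(b) && b$pop == p && b$duration > 0)
        s[(length(s) - b$duration + 1L):length(s)] <- b$N
      s
    }
    res <- list()
    attempts <- 0L
    for (p in POP_ROLES) {
      sel <- NULL
      Hp <- split_H; pp <- split_pos
      if (!is.null(spec$sweep) && spec$sweep$pop == p) {
        sel <- list(pos = as.integer(spec$sweep$pos),
                    s = spec$sweep$s, h = spec$sweep$h)
        repeat {
          attempts <- attempts + 1L
          Hs <- split_H; ps <- split_pos
          j <- match(sel$pos, ps)
          if (is.na(j)) {  # introduce the beneficial allele as a single copy
            col <- matrix(0L, nrow(Hs), 1L)
            col[sample.int(nrow(Hs), 1L), 1L] <- 1L
            Hs <- cbind(Hs, col); ps <- c(ps, sel$pos)
          } else {
            Hs[, j] <- 0L
            Hs[sample.int(nrow(Hs), 1L), j] <- 1L
          }
          out <- wf_evolve_lineage(Hs, ps, sched(p), spec$mu, spec$rho, L, sel)
          if (!out$lost) break
          if (attempts >= spec$max_attempts || spec$loss_action == "fail")
            stop("selected allele lost",
                 if (spec$loss_action == "resample")
                   paste0(" after ", attempts, " attempts") else "")
        }
        res[[p]] <- out
      } else {
        res[[p]] <- wf_evolve_lineage(Hp, pp, sched(p), spec$mu, spec$rho, L)
      }
    }

    # merge lineages on the union of segregating positions
    all_pos <- sort(unique(c(res$Target$pos, res$Control$pos, res$Background$pos)))
    hap_blocks <- lapply(POP_ROLES, function(p) {
      Hp <- res[[p]]$H
      M <- matrix(0L, nrow = length(all_pos), ncol = nrow(Hp))
      j <- match(res[[p]]$pos, all_pos)
      M[j, ] <- t(Hp)
      M
    })
    haps <- do.call(cbind, hap_blocks)
    keep <- rowSums(haps) > 0L & rowSums(haps) < ncol(haps)
    haps <- haps[keep, , drop = FALSE]
    all_pos <- all_pos[keep]
    n_per <- vapply(hap_blocks, ncol, 1L) / 2L
    geno <- haps[, seq(1L, ncol(haps), 2L), drop = FALSE] +
            haps[, seq(2L, ncol(haps), 2L), drop = FALSE]
    pops <- rep(POP_ROLES, times = n_per)
    ids <- unlist(lapply(seq_len(3L), function(k)
      sprintf("%s%02d", substr(POP_ROLES[k], 1, 1), seq_len(n_per[k]))))
    S <- length(all_pos)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, S, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    gm <- genotype_matrix(
      chrom = spec$chrom_name, pos = all_pos, ref = ref, alt = unname(alt),
      geno = geno, sample_ids = ids, pop_labels = pops,
      qual = rep(100, S), mean_dp = rep(30, S),
      haplotypes = haps, phased = TRUE)
    freqs <- vapply(POP_ROLES, function(p) site_counts(gm, p)$p,
                    numeric(S))
    sweep_final <- NULL
    swin <- integer(0)
    if (!is.null(spec$sweep)) {
      i <- match(as.integer(spec$sweep$pos), all_pos)
      f <- if (is.na(i)) 1 else freqs[i, spec$sweep$pop]  # absent => fixed overall
      sweep_final <- c(spec$sweep,
                       list(final_freq = unname(f), attempts = attempts))
      grid <- window_grid(stats::setNames(L, spec$chrom_name))
      swin <- which(grid$chrom == spec$chrom_name &
                    grid$start <= spec$sweep$pos & spec$sweep$pos < grid$end)
    }
    truth <- structure(list(model = "wright_fisher", spec = unclass(spec),
                            sweep = sweep_final, sweep_window_ids = swin,
                            pop_freqs = freqs),
                       class = "SimTruth")
    list(gm = gm, truth = truth)
  })
}
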