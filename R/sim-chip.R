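#' Simulate a differential ChIP experiment
#'
#' Draws a GC-rich genome with AT-boosted binding sites, then per-sample
#' fragment sets in a two-condition replicated design. Background fragment
#' centres follow a gamma-modulated Poisson process (gamma factors i.i.d. per
#' `block_size` bp block and per sample), so counts in analysis-scale windows
#' are negative-binomially overdispersed with dispersion `config$dispersion`;
#' enriched sites draw `(fold - 1)` times extra fragments with a per-site
#' gamma factor. Expected totals equal `library_sizes`.
#'
#' @param config a [chip_sim_config()].
#' @return list with `fragments` (named list of [GenomicRanges::GRanges], one
#'   per sample), `genome` (a [Biostrings::DNAStringSet] with one contig
#'   "chr"), `samples` (data.frame: `sample`, `condition`, `rep`), `sites`
#'   (truth data.frame: `site_id`, `start`, `end` in 0-based half-open
#'   coordinates plus per-condition fold), and `config`.
#' @export
simulate_chip <- function(config) {
  stopifnot(inherits(config, "chip_sim_config"))
  with_seed(config$seed, {
    G <- config$genome_length
    phi <- config$dispersion
    L <- config$fragment_length
    n_cond <- length(config$conditions)

    # --- site placement (0-based half-open), margin away from contig ends,
    # no two sites within one background window of each other
    sites <- integer(0)
    if (config$n_sites > 0) {
      margin <- 2500L
      min_gap <- 2500L
      tries <- 0L
      while (length(sites) < config$n_sites) {
        cand <- as.integer(stats::runif(1, margin, G - margin - config$site_width))
        if (all(abs(cand - sites) >= min_gap + config$site_width)) {
          sites <- c(sites, cand)
        }
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("could not place non-overlapping sites; genome too small",
               call. = FALSE)
        }
      }
      sites <- sort(sites)
    }
    site_df <- if (config$n_sites > 0) {
      data.frame(site_id = sprintf("site%02d", seq_along(sites)),
                 start = sites, end = sites + config$site_width)
    } else {
      data.frame(site_id = character(0), start = integer(0), end = integer(0))
    }
    for (ci in seq_len(n_cond)) {
      site_df[[paste0("fold_", config$conditions[ci])]] <-
        if (config$n_sites > 0) config$enrichment_fold[, ci] else numeric(0)
    }

    # --- genome sequence: per-base AT probability 1 - gc, boosted in sites
    at_bg <- 1 - config$gc_background
    p <- c(at_bg / 2, at_bg / 2, (1 - at_bg) / 2, (1 - at_bg) / 2)
    seq_chr <- sample(c("A", "T", "G", "C"), G, replace = TRUE, prob = p)
    if (config$n_sites > 0 && config$site_at_boost > 0) {
      at_site <- min(1, at_bg + config$site_at_boost)
      ps <- c(at_site / 2, at_site / 2, (1 - at_site) / 2, (1 - at_site) / 2)
      for (s in sites) {
        idx <- (s + 1):(s + config$site_width)
        seq_chr[idx] <- sample(c("A", "T", "G", "C"), config$site_width,
                               replace = TRUE, prob = ps)
      }
    }
    genome <- Biostrings::DNAStringSet(paste(seq_chr, collapse = ""))
    names(genome) <- "chr"

    # --- fragments per sample
    n_blocks <- ceiling(G / config$block_size)
    block_start <- (seq_len(n_blocks) - 1) * config$block_size
    block_len <- pmin(config$block_size, G - block_start)
    cond_of <- rep(seq_len(n_cond), each = config$n_reps)
    samples <- data.frame(
      sample = paste0(config$conditions[cond_of], "_rep",
                      rep(seq_len(config$n_reps), times = n_cond)),
      condition = config$conditions[cond_of],
      rep = rep(seq_len(config$n_reps), times = n_cond))

    frag_list <- vector("list", nrow(samples))
    for (j in seq_len(nrow(samples))) {
      ci <- cond_of[j]
      extra_mass <- if (config$n_sites > 0) {
        sum(config$site_width * (config$enrichment_fold[, ci] - 1))
      } else 0
      lambda <- config$library_sizes[j] / (G + extra_mass)  # base centres/bp
      gb <- if (phi > 0) {
        stats::rgamma(n_blocks, shape = 1 / phi, scale = phi)
      } else rep(1, n_blocks)
      nb <- stats::rpois(n_blocks, lambda * block_len * gb)
      centres <- stats::runif(sum(nb),
                              rep(block_start, nb), rep(block_start + block_len, nb))
      if (config$n_sites > 0) {
        gs <- if (phi > 0) {
          stats::rgamma(config$n_sites, shape = 1 / phi, scale = phi)
        } else rep(1, config$n_sites)
        mu_extra <- lambda * config$site_width *
          (config$enrichment_fold[, ci] - 1) * gs
        ns <- stats::rpois(config$n_sites, mu_extra)
        if (sum(ns) > 0) {
          centres <- c(centres, stats::runif(
            sum(ns), rep(sites, ns), rep(sites + config$site_width, ns)))
        }
      }
      start0 <- pmax(0L, pmin(G - L, as.integer(round(centres - L / 2))))
      gr <- GenomicRanges::GRanges(
        "chr", IRanges::IRanges(start = start0 + 1L, width = L),
        strand = sample(c("+", "-"), length(start0), replace = TRUE))
      GenomeInfoDb::seqlengths(gr) <- c(chr = G)
      frag_list[[j]] <- sort(gr)
    }
    names(frag_list) <- samples$sample
    list(fragments = frag_list, genome = genome, samples = samples,
         sites = site_df, config = config)
  })
}
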