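#' Simulator configuration
#'
#' Parameters of the diploid-pair simulator. Two experimental designs are
#' supported: [simulate_table1_pair()] mutates four reference copies
#' independently and pairs them into two diploids; [simulate_table2_pair()]
#' builds two diploids carrying the *same* heterozygous variants but
#' recombined at independent block boundaries, plus a fixed number of
#' extra, independent per-strand mutations whose count is recorded as
#' ground truth.
#'
#' @param length Reference length in bases (ignored if `reference` given).
#' @param reference Optional reference sequence (string); defaults to a
#'   uniform random sequence over `alphabet`.
#' @param variant_rate Shared heterozygous variants per base (design 2).
#' @param variant_snp_frac Fraction of variants that are SNPs; the rest are
#'   single-base deletions.
#' @param mutation_rate Independent mutations per base per strand copy
#'   (design 1); same SNP/deletion mix as variants.
#' @param mutations Count of extra independent per-strand substitutions
#'   (design 2).
#' @param block_size Recombination block size in bases; each diploid's two
#'   strands may switch orientation at every block boundary with
#'   probability 0.5 ("recombined freely").
#' @param seed Integer seed; fixed seed gives a byte-identical record.
#' @param alphabet Symbol set of the reference.
#' @param min_separation Minimum distance (bases) enforced between planted
#'   events by rejection sampling, keeping them non-overlapping so that
#'   each contributes its own unit of distance.
#' @param allow_collisions Drop the separation constraint (events may
#'   collide; the recorded counts still reflect what was applied).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(length = 10000L, reference = NULL,
                       variant_rate = 0.01, variant_snp_frac = 0.9,
                       mutation_rate = 0.005, mutations = 20L,
                       block_size = 200L, seed = NULL,
                       alphabet = c("a", "c", "g", "t"),
                       min_separation = 5L, allow_collisions = FALSE) {
  stopifnot(length >= 1L, block_size >= 1L, mutations >= 0L,
            min_separation >= 1L)
  for (r in c(variant_rate, variant_snp_frac, mutation_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1)
      stop("rates must lie in [0, 1]")
  }
  if (!is.null(reference)) {
    reference <- norm_seq(reference)
    length <- nchar(reference)
  }
  structure(list(length = as.integer(length), reference = reference,
                 variant_rate = variant_rate,
                 variant_snp_frac = variant_snp_frac,
                 mutation_rate = mutation_rate,
                 mutations = as.integer(mutations),
                 block_size = as.integer(block_size), seed = seed,
                 alphabet = alphabet,
                 min_separation = as.integer(min_separation),
                 allow_collisions = isTRUE(allow_collisions)),
            class = "sim_config")
}

with_sim_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

random_reference <- function(config) {
  if (!is.null(config$reference)) return(config$reference)
  paste(sample(config$alphabet, config$length, replace = TRUE), collapse = "")
}

# Rejection-sample `n` positions in 1..len at pairwise distance >=
# min_sep from each other and from `avoid`.
sample_positions <- function(n, len, min_sep, avoid = integer(0),
                             allow_collisions = FALSE) {
  if (n == 0L) return(integer(0))
  if (allow_collisions) return(sample.int(len, n, replace = TRUE))
  taken <- avoid
  out <- integer(0)
  tries <- 0L
  while (length(out) < n && tries < 200L * n + 1000L) {
    p <- sample.int(len, 1L)
    tries <- tries + 1L
    if (!length(taken) || min(abs(taken - p)) >= min_sep) {
      taken <- c(taken, p)
      out <- c(out, p)
    }
  }
  if (length(out) < n)
    stop("could not place ", n, " separated events on a length-", len,
         " reference; lower the rates or min_separation")
  sort(out)
}

# Event table: pos (reference coordinate), type ("snp"/"del"), alt.
draw_events <- function(pos, snp_frac, ref_chars, alphabet) {
  if (!length(pos))
    return(data.frame(pos = integer(0), type = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  type <- ifelse(runif(length(pos)) < snp_frac, "snp", "del")
  alt <- vapply(seq_along(pos), function(i) {
    if (type[i] == "del") return("")
    sample(setdiff(alphabet, ref_chars[pos[i]]), 1L)
  }, "")
  data.frame(pos = pos, type = type, alt = alt, stringsAsFactors = FALSE)
}

# Apply an event table (all positions distinct) to the reference.
apply_events <- function(ref_chars, events) {
  if (nrow(events)) {
    subs <- events[events$type == "snp", , drop = FALSE]
    ref_chars[subs$pos] <- subs$alt
    dels <- events$pos[events$type == "del"]
    if (length(dels)) ref_chars <- ref_chars[-dels]
  }
  paste(ref_chars, collapse = "")
}

align_pair <- function(a, b) {
  banded_edit_distance(a, b, traceback = TRUE)$alignment
}

new_sim_record <- function(design, config, reference, haps, events,
                           variants = NULL, breakpoints = NULL, n_mutations) {
  structure(list(design = design,
                 reference = reference,
                 haplotypes = haps,
                 diploid1 = align_pair(haps[["d1_a"]], haps[["d1_b"]]),
                 diploid2 = align_pair(haps[["d2_a"]], haps[["d2_b"]]),
                 events = events, variants = variants,
                 breakpoints = breakpoints,
                 n_mutations = n_mutations,
                 seed = config$seed, config = config),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record> design:", x$design, " reference length:",
      nchar(x$reference), "\n")
  cat("  planted mutations:", x$n_mutations, "\n")
  if (!is.null(x$variants))
    cat("  shared variants:", nrow(x$variants), "\n")
  invisible(x)
}

#' Simulate two independently mutated diploids (design 1)
#'
#' Four copies of the reference are mutated independently (SNPs and
#' single-base deletions at `mutation_rate` per base) and grouped into two
#' diploids; each diploid is stored as the optimal unit-cost pair-wise
#' alignment of its two copies. The recorded mutation count is the number
#' of events actually applied after rejection of overlapping placements.
#'
#' @param config A [sim_config()].
#' @return A `sim_record`: reference, the four haplotypes (`d1_a`, `d1_b`,
#'   `d2_a`, `d2_b`), the two diploid alignments, the per-strand event
#'   tables and the planted mutation count.
#' @export
simulate_table1_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    reference <- random_reference(config)
    ref_chars <- chars(reference)
    n <- nchar(reference)
    strands <- c("d1_a", "d1_b", "d2_a", "d2_b")
    events <- list(); haps <- list()
    for (s in strands) {
      k <- rbinom(1L, n, config$mutation_rate)
      pos <- sample_positions(k, n, config$min_separation,
                              allow_collisions = config$allow_collisions)
      ev <- draw_events(pos, config$variant_snp_frac, ref_chars,
                        config$alphabet)
      ev <- ev[!duplicated(ev$pos), , drop = FALSE]
      events[[s]] <- ev
      haps[[s]] <- apply_events(ref_chars, ev)
    }
    new_sim_record("table1", config, reference, haps, events,
                   n_mutations = sum(vapply(events, nrow, 0L)))
  })
}

#' Simulate two diploids sharing variants, recombined differently (design 2)
#'
#' Two founder haplotypes are derived from the reference: every shared
#' heterozygous variant (SNP or single-base deletion at `variant_rate` per
#' base) is assigned to one founder. Each diploid copies the founders
#' block-wise, switching orientation at each `block_size` boundary with
#' probability 0.5, so both diploids contain the same variants but in
#' different phase. Finally `mutations` extra substitutions are planted,
#' each on one uniformly chosen strand of one diploid, kept
#' `min_separation` bases away from every variant and from each other.
#' Each such substitution is absent from the other diploid, so under free
#' recombination the synchronized distance between the two diploids equals
#' the planted mutation count.
#'
#' @param config A [sim_config()].
#' @return A `sim_record`; `breakpoints` holds each diploid's block
#'   orientation switch coordinates (reference positions where the strand
#'   copy changes founder).
#' @export
simulate_table2_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    reference <- random_reference(config)
    ref_chars <- chars(reference)
    n <- nchar(reference)

    n_var <- rbinom(1L, n, config$variant_rate)
    vpos <- sample_positions(n_var, n, config$min_separation,
                             allow_collisions = config$allow_collisions)
    variants <- draw_events(vpos, config$variant_snp_frac, ref_chars,
                            config$alphabet)
    variants$founder <- sample(0:1, nrow(variants), replace = TRUE)

    mpos <- sample_positions(config$mutations, n, config$min_separation,
                             avoid = vpos,
                             allow_collisions = config$allow_collisions)
    mutations <- draw_events(mpos, 1.0, ref_chars, config$alphabet)  # subs only
    strands <- c("d1_a", "d1_b", "d2_a", "d2_b")
    mutations$strand <- sample(strands, nrow(mutations), replace = TRUE)

    n_blocks <- ceiling(n / config$block_size)
    orient <- list()
    breakpoints <- list()
    for (d in c("d1", "d2")) {
      o <- integer(n_blocks)
      o[1L] <- sample(0:1, 1L)
      if (n_blocks > 1L) {
        sw <- runif(n_blocks - 1L) < 0.5
        for (bidx in 2:n_blocks) o[bidx] <- if (sw[bidx - 1L]) 1L - o[bidx - 1L] else o[bidx - 1L]
      }
      orient[[d]] <- o
      breakpoints[[d]] <- (which(diff(o) != 0L)) * config$block_size + 1L
    }

    block_of <- function(p) (p - 1L) %/% config$block_size + 1L
    events <- list(); haps <- list()
    for (s in strands) {
      d <- substr(s, 1L, 2L)
      founder_of_strand <- if (endsWith(s, "_a")) orient[[d]][block_of(variants$pos)]
                           else 1L - orient[[d]][block_of(variants$pos)]
      carried <- variants[variants$founder == founder_of_strand,
                          c("pos", "type", "alt"), drop = FALSE]
      mut <- mutations[mutations$strand == s, c("pos", "type", "alt"),
                       drop = FALSE]
      ev <- rbind(carried, mut)
      ev <- ev[order(ev$pos), , drop = FALSE]
      ev <- ev[!duplicated(ev$pos), , drop = FALSE]
      events[[s]] <- ev
      haps[[s]] <- apply_events(ref_chars, ev)
    }
    rec <- new_sim_record("table2", config, reference, haps, events,
                          variants = variants, breakpoints = breakpoints,
                          n_mutations = nrow(mutations))
    rec$mutations <- mutations
    rec
  })
}
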