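# Constant flanks placing a 40-nt region at read positions 32-71, the
# typical geometry of an amplicon whose randomized library is embedded
# between primer-binding sites.
.default_left_flank  <- "GGACAGCTACGATCGGTAACTGCATGCTAGC"  # 31 nt
.default_right_flank <- "CGATCCAGTT"                        # 10 nt

#' Configuration for a simulated selection experiment
#'
#' Describes a multi-round in vitro selection/evolution experiment with
#' known ground truth: a handful of founder sequences whose fractional
#' abundances follow programmed per-round trajectories, against a
#' background of random library members. Founder reads acquire random
#' substitutions (a mutant cloud), reads carry a two-state quality
#' profile (whole-read good or bad), and the randomized region is
#' embedded between constant flanks, optionally reverse-complemented to
#' emulate reverse sequencing runs.
#'
#' The defaults emulate a typical ribozyme selection read out over four
#' rounds: a 40-nt randomized region at read positions 32-71, 10,000
#' reads per round, five founders whose most abundant trajectory rises
#' 0.01 -> 0.05 -> 0.25 -> 0.40 (enrichment becoming evident in round
#' 3), 5% low-quality reads, and a 0.5% per-base substitution rate.
#'
#' @param library_length Length of the randomized region (default 40).
#' @param n_rounds Number of selection rounds (1..10; default 4).
#' @param founders Character vector of founder region sequences; by
#'   default 5 founders are drawn uniformly at random from the seed.
#' @param founder_fractions Numeric matrix, founders x rounds: target
#'   fractional abundance of each founder in each round. Column sums
#'   must be <= 1; the remainder is random background.
#' @param reads_per_round Reads emitted per round (default 10000).
#' @param per_base_error_rate Per-base substitution probability applied
#'   to founder reads (default 0.005); background reads are already
#'   random.
#' @param q_good,q_bad Phred score assigned to every base of a
#'   good-quality / bad-quality read (defaults 37 and 12).
#' @param p_bad_read Probability a read is bad quality (default 0.05);
#'   bad reads fail the conventional 98% / Q20 filter, good reads pass.
#' @param left_flank,right_flank Constant sequences surrounding the
#'   region (defaults place the region at positions 32-71).
#' @param orientation `"forward"` or `"reverse"`: reverse emits each
#'   read as the reverse complement of flank+region+flank.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(library_length = 40L,
                              n_rounds = 4L,
                              founders = NULL,
                              founder_fractions = NULL,
                              reads_per_round = 10000L,
                              per_base_error_rate = 0.005,
                              q_good = 37L, q_bad = 12L,
                              p_bad_read = 0.05,
                              left_flank = .default_left_flank,
                              right_flank = .default_right_flank,
                              orientation = c("forward", "reverse"),
                              seed = 42L) {
  orientation <- match.arg(orientation)
  stopifnot(library_length >= 1, n_rounds >= 1, n_rounds <= 10,
            reads_per_round >= 1,
            per_base_error_rate >= 0, per_base_error_rate < 1,
            p_bad_read >= 0, p_bad_read <= 1,
            q_good >= 0, q_good <= 93, q_bad >= 0, q_bad <= 93)
  if (is.null(founder_fractions)) {
    founder_fractions <- default_trajectories(n_rounds)
  }
  founder_fractions <- as.matrix(founder_fractions)
  if (ncol(founder_fractions) != n_rounds) {
    stop("founder_fractions must have one column per round", call. = FALSE)
  }
  if (is.null(founders)) {
    founders <- withr::with_seed(seed, {
      random_dna(nrow(founder_fractions), library_length)
    })
  }
  stopifnot(length(founders) == nrow(founder_fractions),
            all(nchar(founders) == library_length))
  bg <- 1 - colSums(founder_fractions)
  if (any(founder_fractions < 0) || any(bg < -1e-9)) {
    stop("per-round founder fractions plus background must sum to 1 ",
         "with no negative components", call. = FALSE)
  }
  structure(
    list(library_length = as.integer(library_length),
         n_rounds = as.integer(n_rounds),
         founders = founders, founder_fractions = founder_fractions,
         background_fraction = pmax(bg, 0),
         reads_per_round = as.integer(reads_per_round),
         per_base_error_rate = per_base_error_rate,
         q_good = as.integer(q_good), q_bad = as.integer(q_bad),
         p_bad_read = p_bad_read,
         left_flank = left_flank, right_flank = right_flank,
         orientation = orientation, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Five founder families with enrichment taking off in the third round;
# trajectories are linearly interpolated for other round counts.
default_trajectories <- function(n_rounds) {
  base <- rbind(
    c(0.010, 0.050, 0.250, 0.400),
    c(0.005, 0.020, 0.100, 0.150),
    c(0.002, 0.010, 0.050, 0.080),
    c(0.001, 0.005, 0.030, 0.050),
    c(0.001, 0.005, 0.020, 0.040)
  )
  if (n_rounds == 4L) return(base)
  xout <- seq(1, 4, length.out = n_rounds)
  out <- vapply(seq_len(nrow(base)), function(i) {
    stats::approx(seq_len(4L), base[i, ], xout = xout)$y
  }, numeric(n_rounds))
  matrix(t(out), nrow = nrow(base), ncol = n_rounds)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_regions <- function(regions, rate) {
  if (rate == 0 || length(regions) == 0L) return(regions)
  L <- nchar(regions[1L])
  chars <- matrix(unlist(strsplit(regions, ""), use.names = FALSE),
                  nrow = length(regions), ncol = L, byrow = TRUE)
  hits <- which(matrix(stats::runif(length(chars)) < rate,
                       nrow = nrow(chars)))
  if (length(hits) > 0L) {
    bases <- c("A", "C", "G", "T")
    # substitute with one of the three other bases
    cur <- chars[hits]
    repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                   character(1), USE.NAMES = FALSE)
    chars[hits] <- repl
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Simulate a multi-round selection experiment with ground truth
#'
#' Writes one FASTQ file per round and returns the exact ground truth
#' needed to validate every pipeline stage: the emitted region sequence,
#' origin (founder index or background) and quality state of every
#' read. Reads are drawn multinomially from the programmed founder /
#' background fractions, founder regions are mutated at the configured
#' per-base rate, and each read is emitted as
#' `left_flank + region + right_flank` (reverse-complemented for
#' reverse orientation) with a two-state quality string. The output is
#' byte-identical across runs with the same config.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param gzip Write gzip-compressed FASTQ (default `FALSE`).
#' @return A list of class `simulation` with `paths` (FASTQ file per
#'   round), `reads` (tibble `round`, `read_id`, `origin`, `region`,
#'   `good_quality`), `config`.
#' @export
simulate_selection <- function(config, dir = tempfile("selexr_sim_"),
                               gzip = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_f <- length(config$founders)
  withr::local_seed(config$seed)

  paths <- character(config$n_rounds)
  truth <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    probs <- c(config$founder_fractions[, r], config$background_fraction[r])
    counts <- as.integer(stats::rmultinom(1L, config$reads_per_round, probs))

    origin <- rep(c(seq_len(n_f), 0L), times = counts) # 0 = background
    regions <- character(config$reads_per_round)
    for (f in seq_len(n_f)) {
      idx <- which(origin == f)
      regions[idx] <- mutate_regions(rep(config$founders[f], length(idx)),
                                     config$per_base_error_rate)
    }
    bg_idx <- which(origin == 0L)
    regions[bg_idx] <- random_dna(length(bg_idx), config$library_length)

    shuffle <- sample.int(config$reads_per_round)
    origin <- origin[shuffle]
    regions <- regions[shuffle]

    good <- stats::runif(config$reads_per_round) >= config$p_bad_read
    full <- paste0(config$left_flank, regions, config$right_flank)
    if (config$orientation == "reverse") {
      full <- reverse_complement(full)
    }
    read_len <- nchar(full[1L])
    qchr_good <- strrep(intToUtf8(config$q_good + 33L), read_len)
    qchr_bad <- strrep(intToUtf8(config$q_bad + 33L), read_len)
    qual <- ifelse(good, qchr_good, qchr_bad)
    ids <- sprintf("sim_round%d_read%06d", r, seq_len(config$reads_per_round))

    path <- file.path(dir, sprintf("round%d.fastq%s", r,
                                   if (gzip) ".gz" else ""))
    write_fastq(tibble::tibble(read_id = ids, sequence = full,
                               quality = qual), path)
    paths[r] <- path
    truth[[r]] <- tibble::tibble(round = r, read_id = ids, origin = origin,
                                 region = regions, good_quality = good)
  }
  structure(
    list(paths = paths, reads = dplyr::bind_rows(truth), config = config),
    class = "simulation"
  )
}

#' Ground-truth dereplicated table for one simulated round
#'
#' The exact multiset of region sequences a correct pipeline (quality
#' filter at the conventional 98% / Q20 cutoff, trim to the region,
#' orientation correction, dereplication) should recover for one round:
#' regions of good-quality reads, counted and ranked like
#' [dereplicate()].
#'
#' @param sim A [simulate_selection()] result.
#' @param round Round number.
#' @return Tibble `rank`, `sequence`, `reads`.
#' @export
ground_truth_table <- function(sim, round) {
  stopifnot(inherits(sim, "simulation"))
  sub <- sim$reads[sim$reads$round == round & sim$reads$good_quality, ]
  dereplicate(sub$region)
}

#' Ground-truth fractional abundance of each founder per round
#'
#' Fraction of good-quality reads per round whose region is exactly the
#' (unmutated) founder sequence — the quantity the top-sequence and
#' cluster-peak trackers estimate.
#'
#' @param sim A [simulate_selection()] result.
#' @return Tibble `founder`, `sequence`, `round`, `fraction`.
#' @export
ground_truth_fractions <- function(sim) {
  stopifnot(inherits(sim, "simulation"))
  founders <- sim$config$founders
  rows <- lapply(seq_len(sim$config$n_rounds), function(r) {
    sub <- sim$reads[sim$reads$round == r & sim$reads$good_quality, ]
    frac <- vapply(founders, function(f) mean(sub$region == f), numeric(1),
                   USE.NAMES = FALSE)
    tibble::tibble(founder = seq_along(founders), sequence = founders,
                   round = r, fraction = frac)
  })
  dplyr::bind_rows(rows)
}

#' Pre-processing configuration matching a simulation
#'
#' Builds the [preprocess_config()] that exactly inverts a simulation's
#' read construction: conventional 98% / Q20 quality filter, positional
#' trim to the embedded region, and the simulation's orientation.
#'
#' @param config A [simulation_config()].
#' @return A `preprocess_config`.
#' @export
sim_preprocess_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  # in a reverse run the emitted read is revcomp(left+region+right), so
  # the region sits after the reverse complement of the right flank
  start <- if (config$orientation == "reverse") {
    nchar(config$right_flank) + 1L
  } else {
    nchar(config$left_flank) + 1L
  }
  preprocess_config(
    quality_cutoff = 98, q_threshold = 20L,
    trim_mode = "positions",
    trim_start = start, trim_end = start + config$library_length - 1L,
    orientation = config$orientation
  )
}
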