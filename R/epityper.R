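# In-silico model of mass-spectrometric bisulfite methylation profiling
# (EpiTYPER/MassARRAY style): bisulfite conversion, T-specific cleavage of
# the reverse-complement transcript, fragment mass prediction with the
# 16 Da per-methylated-CpG shift, CpG-unit mapping and intensity-ratio
# quantification.

# Average ribonucleotide residue masses (Da) and the terminal water added
# once per fragment.  The testable contract is the 16.00 Da methylation
# shift and mass additivity, not absolute calibrated masses.
RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
TERMINAL_WATER <- 18.02
METHYL_SHIFT <- 16.00

#' Define an amplicon for in-silico methylation profiling
#'
#' @param name amplicon name.
#' @param sequence DNA string (A/C/G/T) on the assayed strand.
#' @param cpg_positions 1-based positions of the 'C' of each CpG
#'   dinucleotide in \code{sequence}.
#' @param start genomic start coordinate (bookkeeping only).
#' @param strand \code{"+"} or \code{"-"} (bookkeeping only).
#' @return an \code{amplicon} object.
#' @export
amplicon <- function(name, sequence, cpg_positions = find_cpg_sites(sequence),
                     start = 1L, strand = "+") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence)) {
    stop("sequence must be a non-empty A/C/G/T string")
  }
  cpg_positions <- as.integer(sort(cpg_positions))
  chars <- strsplit(sequence, "")[[1]]
  for (p in cpg_positions) {
    if (p < 1L || p >= nchar(sequence) || chars[p] != "C" ||
        chars[p + 1L] != "G") {
      stop("cpg_position ", p, " is not the C of a CpG dinucleotide")
    }
  }
  structure(list(name = name, sequence = sequence,
                 cpg_positions = cpg_positions, start = start,
                 strand = strand), class = "amplicon")
}

#' Locate CpG sites in a sequence
#' @param sequence DNA string.
#' @return 1-based positions of CpG 'C's.
#' @export
find_cpg_sites <- function(sequence) {
  m <- gregexpr("CG", toupper(sequence), fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Read an amplicon from FASTA plus a YAML sidecar
#'
#' The sidecar carries \code{name}, optional \code{strand}, \code{start} and
#' \code{cpg_positions}; CpG positions default to every CG dinucleotide.
#'
#' @param fasta path to a single-record FASTA file.
#' @param sidecar path to the YAML sidecar (optional).
#' @return an \code{amplicon}.
#' @export
read_amplicon <- function(fasta, sidecar = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA amplicons")
  }
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one FASTA record in ", fasta)
  meta <- if (!is.null(sidecar)) yaml::read_yaml(sidecar) else list()
  seqc <- as.character(ss[[1]])
  amplicon(name = meta$name %||% names(ss)[1],
           sequence = seqc,
           cpg_positions = meta$cpg_positions %||% find_cpg_sites(seqc),
           start = meta$start %||% 1L,
           strand = meta$strand %||% "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bisulfite-convert a sequence in silico
#'
#' Every cytosine deaminates to thymine except CpG cytosines listed as
#' methylated, which remain cytosine.  Length is preserved.
#'
#' @param seq DNA string.
#' @param methylated_cpg_positions 1-based positions of methylated CpG 'C's.
#' @return converted DNA string.
#' @export
bisulfite_convert <- function(seq, methylated_cpg_positions = integer(0)) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in methylated_cpg_positions) {
    if (p < 1L || p >= length(chars) || chars[p] != "C" ||
        chars[p + 1L] != "G") {
      stop("methylated position ", p, " is not a CpG 'C'")
    }
  }
  conv <- ifelse(chars == "C", "T", chars)
  conv[as.integer(methylated_cpg_positions)] <- "C"
  paste(conv, collapse = "")
}

#' Reverse-complement transcript of a (converted) DNA sequence
#'
#' Models in-vitro transcription from the tagged reverse strand: the
#' returned RNA is the reverse complement of the input with U for A.
#'
#' @param seq DNA string.
#' @return RNA string (A/C/G/U), 5' to 3'.
#' @export
rc_transcript <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  comp <- c(A = "U", C = "G", G = "C", T = "A")
  paste(comp[chars], collapse = "")
}

#' Base-specifically cleave a transcript after every U
#'
#' Simulates the RNase T-cleavage reaction: the transcript is cut 3' of
#' every U; fragments are returned 5' to 3' and concatenate exactly to the
#' input.
#'
#' @param transcript RNA string (A/C/G/U); alternatively a DNA string, in
#'   which case the reverse-complement transcript is cleaved (set
#'   \code{input = "dna"}).
#' @param input \code{"transcript"} (default) or \code{"dna"}.
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end}
#'   (1-based positions on the transcript), one row per fragment.
#' @export
cleave_fragments <- function(transcript, input = c("transcript", "dna")) {
  input <- match.arg(input)
  if (input == "dna") transcript <- rc_transcript(transcript)
  transcript <- toupper(transcript)
  if (!nzchar(transcript)) stop("empty transcript")
  chars <- strsplit(transcript, "")[[1]]
  cuts <- which(chars == "U")
  ends <- unique(c(cuts, length(chars)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(
    sequence = vapply(seq_along(ends), function(i)
      paste(chars[starts[i]:ends[i]], collapse = ""), character(1)),
    start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Predicted mass of a cleavage fragment
#'
#' Sum of average ribonucleotide residue masses plus terminal water, plus
#' 16.00 Da per methylated CpG (methylation manifests as a G-for-A
#' substitution on the cleaved strand).
#'
#' @param sequence fragment RNA string in its unmethylated state (A at CpG
#'   positions).
#' @param n_methylated number of methylated CpGs carried by the fragment.
#' @param cpg_count number of CpG sites on the fragment (bounds
#'   \code{n_methylated}); defaults to \code{n_methylated}.
#' @return mass in daltons.
#' @export
fragment_mass <- function(sequence, n_methylated = 0L,
                          cpg_count = n_methylated) {
  if (n_methylated < 0L || n_methylated > cpg_count) {
    stop("n_methylated must be between 0 and cpg_count (", cpg_count, ")")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) && !all(chars %in% names(RESIDUE_MASS))) {
    stop("fragment sequence must be A/C/G/U")
  }
  sum(RESIDUE_MASS[chars]) + TERMINAL_WATER + METHYL_SHIFT * n_methylated
}

#' Map CpG sites of an amplicon to measurement units
#'
#' Runs the unmethylated in-silico reaction (conversion, transcription,
#' T-cleavage), assigns each CpG site to its cleavage fragment, and flags
#' ambiguities: sites sharing a fragment form one multi-site unit; distinct
#' CpG-bearing fragments whose full mass ladders (base mass + 16k, k = 0..K)
#' coincide within \code{mass_resolution} are flagged \code{mass_collision}
#' (averaged downstream); fragments any of whose methylated masses collide
#' with a CpG-free fragment are flagged \code{unresolvable} (dropped
#' downstream).
#'
#' Note the cleavage pattern is independent of methylation state: cuts fall
#' after transcript U's, which mirror template A's, and bisulfite conversion
#' only exchanges C/T (transcript G/A) at CpG sites.
#'
#' @param amp an \code{amplicon}.
#' @param mass_resolution minimum resolvable mass difference in daltons.
#' @return data.frame with one row per unit: \code{unit_label} (site indices
#'   joined by "/"), \code{member_sites}, \code{fragment}, \code{base_mass},
#'   \code{cpg_count}, \code{ambiguity_flag}, \code{collision_group}.
#' @export
map_cpg_units <- function(amp, mass_resolution = 1.0) {
  stopifnot(inherits(amp, "amplicon"), mass_resolution > 0)
  n <- nchar(amp$sequence)
  conv <- bisulfite_convert(amp$sequence, integer(0))
  frs <- cleave_fragments(conv, input = "dna")
  # transcript position t corresponds to amplicon position n - t + 1
  site_tpos <- n - amp$cpg_positions + 1L
  frag_of_site <- vapply(site_tpos, function(t)
    which(frs$start <= t & frs$end >= t), integer(1))
  cpg_frags <- sort(unique(frag_of_site))
  units <- lapply(cpg_frags, function(f) {
    sites <- which(frag_of_site == f)
    list(fragment = f,
         member_sites = sites,
         unit_label = paste(sites, collapse = "/"),
         cpg_count = length(sites),
         base_mass = fragment_mass(frs$sequence[f], 0L, 0L))
  })
  flags <- rep("clean", length(units))
  group <- rep(NA_integer_, length(units))
  # ladder collision between CpG-bearing fragments
  ladders <- lapply(units, function(u)
    u$base_mass + METHYL_SHIFT * (0:u$cpg_count))
  if (length(units) > 1L) {
    g <- 0L
    for (i in seq_along(units)[-length(units)]) {
      for (j in (i + 1L):length(units)) {
        li <- ladders[[i]]; lj <- ladders[[j]]
        if (length(li) == length(lj) &&
            all(abs(li - lj) < mass_resolution)) {
          if (is.na(group[i]) && is.na(group[j])) {
            g <- g + 1L; group[c(i, j)] <- g
          } else {
            group[c(i, j)] <- min(group[i], group[j], na.rm = TRUE)
          }
          flags[c(i, j)] <- "mass_collision"
        }
      }
    }
  }
  # methylated-state mass colliding with a CpG-free fragment
  free_masses <- vapply(setdiff(seq_len(nrow(frs)), cpg_frags), function(f)
    fragment_mass(frs$sequence[f], 0L, 0L), numeric(1))
  if (length(free_masses)) {
    for (i in seq_along(units)) {
      meth_masses <- ladders[[i]][-1L]
      if (any(vapply(meth_masses, function(mm)
        any(abs(mm - free_masses) < mass_resolution), logical(1)))) {
        flags[i] <- "unresolvable"
      }
    }
  }
  data.frame(
    unit_label = vapply(units, `[[`, character(1), "unit_label"),
    member_sites = vapply(units, function(u)
      paste(u$member_sites, collapse = ";"), character(1)),
    fragment = vapply(units, `[[`, integer(1), "fragment"),
    base_mass = vapply(units, `[[`, numeric(1), "base_mass"),
    cpg_count = vapply(units, `[[`, integer(1), "cpg_count"),
    ambiguity_flag = flags,
    collision_group = group,
    stringsAsFactors = FALSE)
}

#' Methylation fraction from a per-state intensity ladder
#'
#' For a unit with K CpGs the spectrum carries K+1 peaks (0..K methylated
#' copies); the methylation fraction is the intensity-weighted mean state
#' divided by K: sum(k * I_k) / (K * sum(I_k)).
#'
#' @param intensities numeric vector of length K+1, element k+1 the signal
#'   of the k-methylated state; must be non-negative.
#' @return fraction in [0,1], or \code{NA_real_} when all intensities are 0.
#' @export
quantify_unit <- function(intensities) {
  if (any(intensities < 0)) stop("intensities must be non-negative")
  K <- length(intensities) - 1L
  if (K < 1L) stop("need at least two intensity states")
  tot <- sum(intensities)
  if (tot == 0) return(NA_real_)
  sum((0:K) * intensities) / (K * tot)
}

#' Simulate replicate methylation measurements
#'
#' Replicates are the true fraction plus Gaussian measurement noise, clamped
#' to [0,1]; deterministic under a fixed seed.
#'
#' @param true_fraction methylation fraction in [0,1].
#' @param noise_sd standard deviation of measurement noise on the fraction
#'   scale.
#' @param replicates number of replicates (the assay runs triplicates).
#' @param seed optional integer seed (uses the current RNG stream when NULL).
#' @return numeric vector of replicate fractions.
#' @export
simulate_measurement <- function(true_fraction, noise_sd = 0.02,
                                 replicates = 3L, seed = NULL) {
  stopifnot(true_fraction >= 0, true_fraction <= 1, noise_sd >= 0,
            replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pmin(1, pmax(0, true_fraction + stats::rnorm(replicates, 0, noise_sd)))
}
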