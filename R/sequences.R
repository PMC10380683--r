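# Stand-in sequence realization. The synthesized codon-optimized sequence
# is proprietary, so constructs get deterministic pseudo-random sequences
# whose only guaranteed motifs are the declared restriction sites: SmaI
# (CCCGGG, blunt cutter, recognition centered on the declared cut) and
# AleI (CACNNNNGTG, cut at the center of the degenerate spacer). Spurious
# recognition motifs are masked by resampling bases outside the shared
# overlap so both constructs keep byte-identical overlap content.

SMAI_MOTIF <- "CCCGGG"
ALEI_REGEX <- "CAC[ACGT]{4}GTG"

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Positions (1-based starts) of motif occurrences not explained by the
# declared sites.
spurious_hits <- function(seq, construct) {
  hits <- function(pattern, fixed) {
    g <- gregexpr(pattern, seq, fixed = fixed)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g)
  }
  sm <- hits(SMAI_MOTIF, TRUE)
  al <- hits(ALEI_REGEX, FALSE)
  sm_ok <- construct$smaI - 2L   # declared cut p -> motif starts at p-3 (0-based) = p-2 (1-based)
  al_ok <- construct$aleI - 4L
  list(smaI = setdiff(sm, sm_ok), aleI = setdiff(al, al_ok))
}

#' Realize a construct's nucleotide sequence
#'
#' Deterministic pseudo-random sequence of the construct's length with the
#' SmaI and AleI recognition motifs placed only at the declared sites. The
#' overlap interval content depends on the seed alone, so the 5' and 3'
#' constructs realized under the same seed carry an identical overlap
#' sequence. Spurious recognition motifs are removed by reseampling bases
#' outside the overlap and outside declared-site windows; a motif that
#' cannot be removed indicates a construction bug and raises an error.
#'
#' @param construct an `aav_construct`.
#' @param seed integer seed.
#' @return list with `sequence` (character scalar) and `annotation` (the
#'   element table).
#' @export
realize_sequence <- function(construct, seed) {
  stopifnot(inherits(construct, "aav_construct"))
  L <- construct$length
  ov <- construct$overlap
  # shared overlap stream: seed only
  set.seed(as.integer(seed))
  ov_seq <- strsplit(rand_dna(diff(ov)), "")[[1]]
  # scrub enzyme motifs inside the overlap itself (same scrub on both
  # constructs since it only consumes the shared stream)
  repeat {
    s <- paste(ov_seq, collapse = "")
    h <- c(vapply(as.integer(gregexpr(SMAI_MOTIF, s, fixed = TRUE)[[1]]),
                  identity, integer(1)),
           vapply(as.integer(gregexpr(ALEI_REGEX, s)[[1]]),
                  identity, integer(1)))
    h <- h[h > 0]
    if (!length(h)) break
    ov_seq[h[1] + 2L] <- sample(c("A", "C", "G", "T"), 1)
  }
  # construct-specific remainder
  set.seed(as.integer(seed) + match(construct$identity,
                                    c("five_prime", "three_prime")) * 1000003L)
  x <- strsplit(rand_dna(L), "")[[1]]
  x[(ov[1] + 1L):ov[2]] <- ov_seq
  # plant declared motifs (0-based cut position p: SmaI CCC|GGG occupies
  # p-3..p+2; AleI CACNN|NNGTG occupies p-5..p+4)
  for (p in construct$smaI)
    x[(p - 2L):(p + 3L)] <- strsplit(SMAI_MOTIF, "")[[1]]
  p <- construct$aleI
  x[(p - 4L):(p - 2L)] <- c("C", "A", "C")
  x[(p + 3L):(p + 5L)] <- c("G", "T", "G")
  protected <- c(unlist(lapply(construct$smaI, function(p) (p - 2L):(p + 3L))),
                 (p - 4L):(p + 5L),
                 (ov[1] + 1L):ov[2])
  for (iter in 1:100) {
    sp <- spurious_hits(paste(x, collapse = ""), construct)
    bad <- c(sp$smaI, sp$aleI)
    if (!length(bad)) break
    start <- bad[1]
    span <- start:(start + 9L)  # covers both motif widths
    span <- span[span >= 1 & span <= L & !(span %in% protected)]
    if (!length(span))
      stop_dq("spurious recognition motif cannot be masked (construction bug)",
              "sequence_bug")
    pos <- span[1]
    x[pos] <- sample(setdiff(c("A", "C", "G", "T"), x[pos]), 1)
  }
  sp <- spurious_hits(paste(x, collapse = ""), construct)
  if (length(c(sp$smaI, sp$aleI)))
    stop_dq("spurious recognition motif survived masking (construction bug)",
            "sequence_bug")
  list(sequence = paste(x, collapse = ""), annotation = construct$elements)
}

#' Write realized construct sequences as FASTA
#'
#' @param constructs list of `aav_construct`s (e.g.
#'   [build_default_constructs()]).
#' @param path FASTA output path.
#' @param seed seed passed to [realize_sequence()].
#' @export
write_construct_fasta <- function(constructs, path, seed = 1L) {
  seqs <- lapply(constructs, realize_sequence, seed = seed)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "sequence"))
    names(ss) <- vapply(constructs, `[[`, character(1), "identity")
    Biostrings::writeXStringSet(ss, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", constructs[[i]]$identity), con)
      writeLines(seqs[[i]]$sequence, con)
    }
  }
  invisible(path)
}
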