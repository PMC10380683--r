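# In-silico restriction digestion on structural coordinates. A molecule's
# walk is the concatenation of its unit segments (construct coordinate
# intervals, possibly reversed); HR junctions splice out the internal ITRs
# and one copy of the overlap, ITR junctions retain both ITRs. Digestion
# cuts the walk at every enzyme site; fragments carry the primer sites,
# residual enzyme sites and ITR junctions that fall inside them. Operating
# on coordinates rather than realized sequences keeps digestion exact;
# sequences exist only for export.
#
# Fragment records are flat vector lists (not data.frames) because a
# population can hold thousands of distinct species; per-species digestion
# results are memoized in a session cache keyed by structure and panel.

# Layout of one molecule: unit segments in walk coordinates.
molecule_layout <- function(mol, constructs) {
  n <- length(mol$identities)
  lens <- vapply(mol$identities, function(id) constructs[[id]]$length, numeric(1))
  s <- numeric(n); e <- lens
  for (j in seq_along(mol$junctions)) {
    if (mol$junctions[j] != "HR") next
    i2 <- if (j == n) 1L else j + 1L
    # HR joins (5',+) to (3',+): keep the overlap once, on the 5' side;
    # internal ITRs are resolved by elimination.
    e[j] <- constructs[[mol$identities[j]]]$overlap[2]
    s[i2] <- constructs[[mol$identities[i2]]]$overlap[2]
  }
  wlen <- e - s
  list(identity = mol$identities, orient = mol$orients,
       s = s, e = e, rev = mol$orients == "-",
       wstart = cumsum(c(0, wlen[-n])), total = sum(wlen), n = n)
}

#' Structural cut sites of an enzyme on a molecule
#'
#' SmaI cuts once inside every surviving ITR: the terminal ITRs of every
#' chain end and both ITRs at every ITR-ITR junction; HR junctions carry no
#' ITRs and yield no site. AleI cuts exactly once per vector unit (its site
#' lies outside ITRs and outside the overlap, so it always survives).
#'
#' @param mol a `molecule_species`.
#' @param enzyme `"SmaI"` or `"AleI"`.
#' @param constructs list with `five_prime`/`three_prime` constructs.
#' @return sorted numeric vector of walk positions.
#' @export
cut_sites <- function(mol, enzyme, constructs) {
  enzyme <- match.arg(enzyme, c("SmaI", "AleI"))
  lay <- molecule_layout(mol, constructs)
  out <- numeric(0)
  for (i in seq_len(lay$n)) {
    con <- constructs[[lay$identity[i]]]
    q <- if (enzyme == "SmaI") con$smaI else con$aleI
    q <- q[q > lay$s[i] & q < lay$e[i]]
    if (length(q))
      out <- c(out, if (lay$rev[i]) lay$wstart[i] + (lay$e[i] - q)
               else lay$wstart[i] + (q - lay$s[i]))
  }
  sort(out)
}

# All annotated walk sites of a molecule. Returns flat vectors:
# sites (kind/name/pos/strand) and junctions (jpos/jtype/jclass).
molecule_sites <- function(mol, constructs, panel) {
  lay <- molecule_layout(mol, constructs)
  pr <- panel$primers
  kind <- list(); name <- list(); pos <- list(); strand <- list()
  for (i in seq_len(lay$n)) {
    con <- constructs[[lay$identity[i]]]
    sel <- pr$construct == lay$identity[i] & pr$pos > lay$s[i] & pr$pos < lay$e[i]
    proj <- function(q) if (lay$rev[i]) lay$wstart[i] + (lay$e[i] - q)
                        else lay$wstart[i] + (q - lay$s[i])
    if (any(sel)) {
      st <- pr$strand[sel]
      if (lay$rev[i]) st <- ifelse(st == "+", "-", "+")
      kind[[length(kind) + 1L]] <- rep("primer", sum(sel))
      name[[length(name) + 1L]] <- pr$primer[sel]
      pos[[length(pos) + 1L]] <- proj(pr$pos[sel])
      strand[[length(strand) + 1L]] <- st
    }
    for (enz in c("SmaI", "AleI")) {
      q <- if (enz == "SmaI") con$smaI else con$aleI
      q <- q[q > lay$s[i] & q < lay$e[i]]
      if (length(q)) {
        kind[[length(kind) + 1L]] <- rep(enz, length(q))
        name[[length(name) + 1L]] <- rep(enz, length(q))
        pos[[length(pos) + 1L]] <- proj(q)
        strand[[length(strand) + 1L]] <- rep(NA_character_, length(q))
      }
    }
  }
  n <- lay$n
  njx <- length(mol$junctions)
  jpos <- numeric(njx); jtype <- character(njx); jclass <- rep(NA_character_, njx)
  for (j in seq_len(njx)) {
    i2 <- if (j == n) 1L else j + 1L
    jpos[j] <- if (j == n) lay$total else lay$wstart[i2]
    jtype[j] <- mol$junctions[j]
    if (jtype[j] != "HR") {
      p1 <- end_primer(mol$identities[j], unit_end(mol$orients[j], "right"))
      p2 <- end_primer(mol$identities[i2], unit_end(mol$orients[i2], "left"))
      jclass[j] <- junction_class_label(p1, p2)
    }
  }
  list(lay = lay,
       kind = unlist(kind) %||% character(0),
       name = unlist(name) %||% character(0),
       pos = unlist(pos) %||% numeric(0),
       strand = unlist(strand) %||% character(0),
       jpos = jpos, jtype = jtype, jclass = jclass)
}

new_fragment <- function(length, kind, name, pos, strand, jpos, jtype, jclass,
                         circular = FALSE, transcript_class = NULL) {
  list(length = length, kind = kind, name = name, pos = pos, strand = strand,
       jpos = jpos, jtype = jtype, jclass = jclass, circular = circular,
       transcript_class = transcript_class)
}

# Cut one site/junction inventory at positions `cuts`; returns list of
# fragment records. `total` is the walk length, `circular` the topology.
cut_inventory <- function(total, circular, cuts,
                          kind, name, pos, strand, jpos, jtype, jclass) {
  if (!length(cuts)) {
    if (circular) jpos[jpos == total] <- 0
    return(list(new_fragment(total, kind, name, pos, strand,
                             jpos, jtype, jclass, circular = circular)))
  }
  cuts <- sort(cuts)
  if (!circular) {
    bnd <- c(0, cuts, total)
    sfrag <- findInterval(pos, cuts) + 1L   # sites strictly between cuts
    jfrag <- findInterval(jpos, cuts) + 1L
    nfr <- length(bnd) - 1L
    off <- bnd[-length(bnd)]
    lapply(seq_len(nfr), function(i) {
      ss <- which(sfrag == i); jj <- which(jfrag == i)
      new_fragment(bnd[i + 1L] - bnd[i],
                   kind[ss], name[ss], pos[ss] - off[i], strand[ss],
                   jpos[jj] - off[i], jtype[jj], jclass[jj])
    })
  } else {
    # rotate so the first cut is the origin, then treat as linear
    rot <- function(w) (w - cuts[1]) %% total
    pos2 <- rot(pos); jpos2 <- rot(jpos)
    cuts2 <- sort(rot(cuts))
    bnd <- c(cuts2, total)
    # a site or junction at walk position 0 (the cut origin) cannot exist:
    # cuts never coincide with junction boundaries or primer sites
    sfrag <- findInterval(pos2, cuts2[-1]) + 1L
    jfrag <- findInterval(jpos2, cuts2[-1]) + 1L
    nfr <- length(bnd) - 1L
    off <- bnd[-length(bnd)]
    lapply(seq_len(nfr), function(i) {
      ss <- which(sfrag == i); jj <- which(jfrag == i)
      new_fragment(bnd[i + 1L] - bnd[i],
                   kind[ss], name[ss], pos2[ss] - off[i], strand[ss],
                   jpos2[jj] - off[i], jtype[jj], jclass[jj])
    })
  }
}

# Fragment one molecule species at the given enzymes (no counts).
species_fragments <- function(mol, enzymes, constructs, panel) {
  ms <- molecule_sites(mol, constructs, panel)
  cuts <- ms$pos[ms$kind %in% enzymes]
  keep <- !(ms$kind %in% enzymes)  # consumed by cutting
  cut_inventory(ms$lay$total, mol$topology == "circular", cuts,
                ms$kind[keep], ms$name[keep], ms$pos[keep], ms$strand[keep],
                ms$jpos, ms$jtype, ms$jclass)
}

fragment_key <- function(fr) {
  o <- order(fr$pos, fr$name)
  oj <- order(fr$jpos)
  paste(fr$length,
        paste(fr$name[o], round(fr$pos[o], 6), fr$strand[o], collapse = ";"),
        paste(fr$jtype[oj], fr$jclass[oj], round(fr$jpos[oj], 6), collapse = ";"),
        fr$circular, fr$transcript_class %||% "", sep = " || ")
}

.digest_cache <- new.env(parent = emptyenv())

#' Digest a population or fragment population
#'
#' Splits every molecule at all structural cut sites of the enzyme
#' (complete digestion). Primer sites, residual enzyme sites and ITR
#' junctions are assigned to the fragment containing their coordinate.
#' Host genomes contribute intact Titin reference fragments (neither SmaI
#' nor AleI cuts inside the Titin amplicon). `enzyme = "none"` is the
#' identity pass-through.
#'
#' @param x a `sample_population` or `fragment_population`.
#' @param enzyme `"SmaI"`, `"AleI"` or `"none"`.
#' @param constructs construct list (see [build_default_constructs()]).
#' @param panel an `assay_panel` whose primer sites are tracked.
#' @return object of class `fragment_population`: distinct fragment
#'   classes with lengths, retained sites, contained junctions and counts.
#' @export
digest <- function(x, enzyme, constructs, panel) UseMethod("digest")

#' @export
digest.sample_population <- function(x, enzyme, constructs, panel) {
  enzyme <- match.arg(enzyme, c("SmaI", "AleI", "none"))
  enzymes <- if (enzyme == "none") character(0) else enzyme
  psig <- paste(panel$primers$primer, panel$primers$construct,
                panel$primers$pos, panel$primers$strand, collapse = ",")
  nsp <- length(x$species)
  all_keys <- vector("list", nsp + 1L)
  all_counts <- vector("list", nsp + 1L)
  all_recs <- vector("list", nsp + 1L)
  for (si in seq_len(nsp)) {
    m <- x$species[[si]]
    ck <- paste(structure_string(m), m$topology, enzyme, psig, sep = " @@ ")
    ent <- .digest_cache[[ck]]
    if (is.null(ent)) {
      frs <- species_fragments(m, enzymes, constructs, panel)
      ent <- list(frs = frs, keys = vapply(frs, fragment_key, character(1)))
      .digest_cache[[ck]] <- ent
    }
    all_keys[[si]] <- ent$keys
    all_counts[[si]] <- rep(as.numeric(m$count), length(ent$keys))
    all_recs[[si]] <- ent$frs
  }
  if (x$titin_copies > 0L) {
    pr <- panel$primers[panel$primers$construct == "host", , drop = FALSE]
    ttn <- new_fragment(400, rep("primer", nrow(pr)), pr$primer, pr$pos,
                        pr$strand, numeric(0), character(0), character(0))
    all_keys[[nsp + 1L]] <- "titin_reference"
    all_counts[[nsp + 1L]] <- as.numeric(x$titin_copies)
    all_recs[[nsp + 1L]] <- list(ttn)
  }
  keys <- unlist(all_keys) %||% character(0)
  counts <- unlist(all_counts) %||% numeric(0)
  recs <- unlist(all_recs, recursive = FALSE) %||% list()
  uk <- !duplicated(keys)
  if (length(keys)) {
    idx <- match(keys, keys[uk])
    agg <- as.numeric(rowsum(counts, idx))
  } else agg <- numeric(0)
  structure(list(fragments = recs[uk], counts = agg, enzymes = enzymes),
            class = "fragment_population")
}

#' @export
digest.fragment_population <- function(x, enzyme, constructs, panel) {
  enzyme <- match.arg(enzyme, c("SmaI", "AleI", "none"))
  if (enzyme == "none") return(x)
  frs <- list(); cts <- numeric(0)
  for (i in seq_along(x$fragments)) {
    fr <- x$fragments[[i]]
    cuts <- fr$pos[fr$kind == enzyme]
    keep <- fr$kind != enzyme
    sub <- cut_inventory(fr$length, fr$circular, cuts,
                         fr$kind[keep], fr$name[keep], fr$pos[keep],
                         fr$strand[keep], fr$jpos, fr$jtype, fr$jclass)
    frs <- c(frs, sub)
    cts <- c(cts, rep(x$counts[i], length(sub)))
  }
  keys <- vapply(frs, fragment_key, character(1))
  uk <- !duplicated(keys)
  idx <- match(keys, keys[uk])
  structure(list(fragments = frs[uk],
                 counts = as.numeric(rowsum(cts, idx)),
                 enzymes = union(x$enzymes, enzyme)),
            class = "fragment_population")
}

#' @export
print.fragment_population <- function(x, ...) {
  cat(sprintf("<fragment_population> %d classes, %.0f fragments (enzymes: %s)\n",
              length(x$fragments), sum(x$counts),
              if (length(x$enzymes)) paste(x$enzymes, collapse = "+") else "none"))
  invisible(x)
}

#' Fragment population from a transcript population
#'
#' Transcripts are represented as class-tagged templates detected by the
#' class-specific RT assays.
#'
#' @param tp a `transcript_population`.
#' @return a `fragment_population`.
#' @export
transcript_fragments <- function(tp) {
  stopifnot(inherits(tp, "transcript_population"))
  keep <- which(tp$counts > 0)
  frs <- lapply(names(tp$counts)[keep], function(cl)
    new_fragment(200, character(0), character(0), numeric(0), character(0),
                 numeric(0), character(0), character(0),
                 transcript_class = cl))
  structure(list(fragments = frs, counts = as.numeric(unname(tp$counts[keep])),
                 enzymes = character(0)),
            class = "fragment_population")
}

#' Export a fragment table
#'
#' TSV with one row per fragment class: length, count, retained primer
#' sites, junction classes.
#'
#' @param f a `fragment_population`.
#' @param path output file.
#' @export
write_fragment_table <- function(f, path) {
  df <- data.frame(
    length = vapply(f$fragments, `[[`, numeric(1), "length"),
    count = f$counts,
    sites = vapply(f$fragments, function(fr)
      paste(fr$name[fr$kind == "primer"], collapse = ","), character(1)),
    junctions = vapply(f$fragments, function(fr)
      paste(fr$jclass[!is.na(fr$jclass)], collapse = ","), character(1)))
  df <- df[order(-df$count, df$length), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
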