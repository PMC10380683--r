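# Molecule simulator: synthetic populations of vector-genome molecules with
# the statistical structure the quantification assumes. A molecule is a
# chain of vector-genome units joined by typed junctions: HR (homologous
# recombination of the overlap, internal ITRs resolved by elimination) or
# ITR-ITR junctions in head-to-tail, head-to-head or tail-to-tail
# orientation. Ground truth is kept alongside so estimator recovery is
# well-posed.

JUNCTION_TYPES <- c("HR", "ITR_head_to_tail", "ITR_head_to_head", "ITR_tail_to_tail")
JX_SHORT <- c(HR = "HR", ITR_head_to_tail = "HT", ITR_head_to_head = "HH",
              ITR_tail_to_tail = "TT")

unit_end <- function(orient, side) {
  # side "left"/"right" in walk order; orient "+"/"-"
  if (side == "right") if (orient == "+") "tail" else "head"
  else                 if (orient == "+") "head" else "tail"
}

#' Construct one molecule species
#'
#' @param identities character vector, `"five_prime"`/`"three_prime"` per unit.
#' @param orients character vector of `"+"`/`"-"` per unit.
#' @param junctions character vector of junction types (long names from
#'   `"HR"`, `"ITR_head_to_tail"`, `"ITR_head_to_head"`,
#'   `"ITR_tail_to_tail"`); length `units - 1` (linear) or `units` (circular).
#' @param topology `"linear"` or `"circular"`.
#' @param count number of molecules of this species in the sample.
#' @return object of class `molecule_species`.
#' @export
molecule_species <- function(identities, orients, junctions = character(0),
                             topology = c("linear", "circular"), count = 1L) {
  topology <- match.arg(topology)
  n <- length(identities)
  stopifnot(n >= 1L, length(orients) == n, all(orients %in% c("+", "-")),
            all(identities %in% c("five_prime", "three_prime")),
            all(junctions %in% JUNCTION_TYPES), count >= 0)
  need <- if (topology == "linear") n - 1L else n
  if (length(junctions) != need)
    stop_dq(sprintf("expected %d junctions, got %d", need, length(junctions)),
            "molecule_invalid")
  # orientation/type consistency at every junction
  for (j in seq_along(junctions)) {
    i1 <- j; i2 <- if (j == n) 1L else j + 1L
    e1 <- unit_end(orients[i1], "right"); e2 <- unit_end(orients[i2], "left")
    ty <- junctions[j]
    ok <- switch(ty,
      HR = identities[i1] == "five_prime" && identities[i2] == "three_prime" &&
           orients[i1] == "+" && orients[i2] == "+",
      ITR_head_to_tail = sort(c(e1, e2))[1] == "head" && sort(c(e1, e2))[2] == "tail",
      ITR_head_to_head = e1 == "head" && e2 == "head",
      ITR_tail_to_tail = e1 == "tail" && e2 == "tail")
    if (!ok)
      stop_dq(sprintf("junction %d (%s) inconsistent with flanking ends %s-%s",
                      j, ty, e1, e2), "molecule_invalid")
  }
  structure(list(identities = identities, orients = orients,
                 junctions = junctions, topology = topology,
                 count = as.integer(count)),
            class = "molecule_species")
}

#' Parse a molecule structure string
#'
#' Format: units `5+`/`5-`/`3+`/`3-` separated by junction codes `|HR|`,
#' `|HT|`, `|HH|`, `|TT|`; circular species carry a trailing junction code,
#' e.g. `"5+|HT|3+|HT|"`.
#'
#' @param s structure string.
#' @param count molecule count.
#' @return `molecule_species`.
#' @export
parse_structure <- function(s, count = 1L) {
  circ <- grepl("\\|$", s)
  toks <- strsplit(gsub("\\|$", "", s), "|", fixed = TRUE)[[1]]
  units <- toks[seq(1, length(toks), by = 2)]
  jx <- if (length(toks) > 1) toks[seq(2, length(toks), by = 2)] else character(0)
  long <- names(JX_SHORT)[match(jx, JX_SHORT)]
  molecule_species(
    identities = ifelse(substr(units, 1, 1) == "5", "five_prime", "three_prime"),
    orients = substr(units, 2, 2),
    junctions = long,
    topology = if (circ) "circular" else "linear",
    count = count)
}

#' Structure string of a molecule species
#' @param m a `molecule_species`.
#' @return character scalar, inverse of [parse_structure()].
#' @export
structure_string <- function(m) {
  u <- paste0(ifelse(m$identities == "five_prime", "5", "3"), m$orients)
  jx <- unname(JX_SHORT[m$junctions])
  n <- length(u)
  if (m$topology == "linear") {
    if (n == 1L) u else paste0(paste0(u[-n], "|", jx, "|", collapse = ""), u[n])
  } else {
    paste0(paste0(u, "|", jx, "|", collapse = ""))
  }
}

#' @export
print.molecule_species <- function(x, ...) {
  cat(sprintf("<molecule_species> %s (%s) x %d\n", structure_string(x),
              x$topology, x$count))
  invisible(x)
}

#' Assemble a sample population
#'
#' @param species list of `molecule_species`.
#' @param host_genomes diploid host genome equivalents in the sample; the
#'   Titin reference locus is present at two copies per genome.
#' @return object of class `sample_population`.
#' @export
sample_population <- function(species, host_genomes = 0L) {
  stopifnot(all(vapply(species, inherits, logical(1), "molecule_species")),
            host_genomes >= 0)
  structure(list(species = species,
                 host_genomes = as.integer(host_genomes),
                 titin_copies = 2L * as.integer(host_genomes)),
            class = "sample_population")
}

#' @export
print.sample_population <- function(x, ...) {
  n <- sum(vapply(x$species, `[[`, integer(1), "count"))
  cat(sprintf("<sample_population> %d species, %d molecules, %d host genomes\n",
              length(x$species), n, x$host_genomes))
  invisible(x)
}

#' Simulation parameters
#'
#' @param u5,u3 mean delivered vector genomes per diploid host genome for
#'   the 5' and 3' vector. Defaults (8 and 12) mirror the observed
#'   asymmetry of a higher copy number for the 3' vector.
#' @param hr_fraction theta in `[0,1]`: fraction of the limiting vector's
#'   units consumed into HR-recombined molecules.
#' @param concat_fraction phi in `[0,1]`: fraction of the units remaining
#'   after HR that enter ITR concatemer chains.
#' @param chain_length_p geometric parameter; chain length is
#'   `1 + Geometric(p)` units (mean `1/p`).
#' @param orientation_weights positive weights over the three ITR junction
#'   types (head-to-tail, head-to-head, tail-to-tail); renormalized over the
#'   types compatible with the current chain end.
#' @param host_genomes diploid genome equivalents.
#' @param seed RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(u5 = 8, u3 = 12, hr_fraction = 0.5,
                       concat_fraction = 0.05, chain_length_p = 0.5,
                       orientation_weights = c(1, 1, 1),
                       host_genomes = 10000L, seed = 1L) {
  stopifnot(u5 >= 0, u3 >= 0,
            hr_fraction >= 0, hr_fraction <= 1,
            concat_fraction >= 0, concat_fraction <= 1,
            chain_length_p > 0, chain_length_p <= 1,
            length(orientation_weights) == 3, all(orientation_weights >= 0),
            sum(orientation_weights) > 0, host_genomes >= 0)
  structure(list(u5 = u5, u3 = u3, hr_fraction = hr_fraction,
                 concat_fraction = concat_fraction,
                 chain_length_p = chain_length_p,
                 orientation_weights = orientation_weights,
                 host_genomes = as.integer(host_genomes),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a molecule population with ground truth
#'
#' Draws total delivered units `T5 ~ Poisson(u5 * host_genomes)` and
#' `T3 ~ Poisson(u3 * host_genomes)`; forms
#' `R = round(hr_fraction * min(T5, T3))` HR molecules (one 5' + one 3'
#' unit each, joined by an HR junction with internal ITRs eliminated); of
#' the remaining units, assigns a fraction `concat_fraction` into linear
#' concatemer chains of length `1 + Geometric(chain_length_p)`, with unit
#' identity drawn without replacement from the remaining pools and junction
#' orientation sampled from `orientation_weights` (restricted to the types
#' compatible with the free end of the growing chain); the remainder stays
#' monomeric.
#'
#' @param p a [sim_params()] object.
#' @return list with components `population` (a `sample_population`) and
#'   `truth` (a `ground_truth`: totals `T5`/`T3`, HR count `R`, junction
#'   census `J`, `true_hr = R/min(T5,T3)` and `true_concat` = assay-
#'   detectable ITR junctions over `T5 + T3`).
#' @export
simulate_sample <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  G <- p$host_genomes
  T5 <- stats::rpois(1, p$u5 * G)
  T3 <- stats::rpois(1, p$u3 * G)
  R <- as.integer(round(p$hr_fraction * min(T5, T3)))
  if (R > min(T5, T3))
    stop_dq("HR demand exceeds available units", "sim_invalid")
  n5 <- T5 - R; n3 <- T3 - R; M <- n5 + n3
  C <- as.integer(round(p$concat_fraction * M))

  species <- list()
  jx_census <- data.frame(type = character(0), class = character(0),
                          count = integer(0))
  chain_keys <- character(0)
  used5 <- 0L; used3 <- 0L

  if (C > 0L) {
    lens <- 1L + stats::rgeom(C, p$chain_length_p)
    cum <- cumsum(lens)
    k <- which(cum >= C)[1]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (cum[k] - C)
    if (lens[k] == 0L) lens <- lens[-k]
    Csum <- sum(lens)
    # identities without replacement from the remaining pools
    id5 <- sample.int(M, Csum) <= n5
    used5 <- sum(id5); used3 <- Csum - used5
    chain_id <- rep(seq_along(lens), lens)
    # orientations: first unit of each chain is "+"; at each junction a
    # type is drawn among those compatible with the current free end
    w <- p$orientation_weights  # (HT, HH, TT)
    orient <- logical(Csum)  # TRUE = "+"
    jtype <- character(Csum) # junction preceding unit i (within chain)
    u <- stats::runif(Csum)
    first <- !duplicated(chain_id)
    orient[first] <- TRUE
    for (i in seq_len(Csum)[-1]) {
      if (first[i]) { orient[i] <- TRUE; next }
      if (orient[i - 1L]) {           # free end is a tail: HT or TT
        pht <- w[1] / (w[1] + w[3])
        if (u[i] < pht) { jtype[i] <- "ITR_head_to_tail"; orient[i] <- TRUE }
        else            { jtype[i] <- "ITR_tail_to_tail"; orient[i] <- FALSE }
      } else {                        # free end is a head: HT or HH
        pht <- w[1] / (w[1] + w[2])
        if (u[i] < pht) { jtype[i] <- "ITR_head_to_tail"; orient[i] <- FALSE }
        else            { jtype[i] <- "ITR_head_to_head"; orient[i] <- TRUE }
      }
    }
    utok <- paste0(ifelse(id5, "5", "3"), ifelse(orient, "+", "-"))
    jtok <- unname(JX_SHORT[jtype])
    piece <- ifelse(first, utok, paste0("|", jtok, "|", utok))
    chain_keys <- vapply(split(piece, chain_id), paste0, character(1),
                         collapse = "")
  }

  tab <- if (length(chain_keys)) table(chain_keys) else NULL
  if (R > 0L)
    species <- c(species, list(molecule_species(
      c("five_prime", "three_prime"), c("+", "+"), "HR", count = R)))
  m5 <- n5 - used5; m3 <- n3 - used3
  # length-1 "chains" are structurally monomers: fold them in
  if (!is.null(tab)) {
    for (mono in c("5+", "3+")) {
      i <- match(mono, names(tab))
      if (!is.na(i)) {
        if (mono == "5+") m5 <- m5 + as.integer(tab[i]) else m3 <- m3 + as.integer(tab[i])
        tab <- tab[-i]
      }
    }
    if (!length(tab)) tab <- NULL
  }
  if (m5 > 0L) species <- c(species, list(parse_structure("5+", m5)))
  if (m3 > 0L) species <- c(species, list(parse_structure("3+", m3)))
  if (!is.null(tab))
    species <- c(species,
                 mapply(parse_structure, names(tab), as.integer(tab),
                        SIMPLIFY = FALSE, USE.NAMES = FALSE))

  pop <- sample_population(species, host_genomes = G)
  truth <- ground_truth_metrics(pop)
  if (truth$T5 != T5 || truth$T3 != T3 || truth$R != R)
    stop_dq("internal bookkeeping mismatch", "internal")
  list(population = pop, truth = truth)
}

#' Recompute ground-truth metrics from a population
#'
#' Independent audit: walks the species table alone and recomputes unit
#' totals, HR junction count, the junction census by type and
#' flanking-primer class, and the derived `true_hr` and `true_concat`
#' (assay-detectable ITR junctions over all units).
#'
#' @param pop a `sample_population`.
#' @return object of class `ground_truth`.
#' @export
ground_truth_metrics <- function(pop) {
  stopifnot(inherits(pop, "sample_population"))
  T5 <- 0L; T3 <- 0L; R <- 0L
  cls <- character(0); typ <- character(0); cnt <- integer(0)
  for (m in pop$species) {
    T5 <- T5 + m$count * sum(m$identities == "five_prime")
    T3 <- T3 + m$count * sum(m$identities == "three_prime")
    if (!length(m$junctions)) next
    n <- length(m$identities)
    for (j in seq_along(m$junctions)) {
      if (m$junctions[j] == "HR") { R <- R + m$count; next }
      i1 <- j; i2 <- if (j == n) 1L else j + 1L
      p1 <- end_primer(m$identities[i1], unit_end(m$orients[i1], "right"))
      p2 <- end_primer(m$identities[i2], unit_end(m$orients[i2], "left"))
      cls <- c(cls, junction_class_label(p1, p2))
      typ <- c(typ, m$junctions[j])
      cnt <- c(cnt, m$count)
    }
  }
  J <- if (length(cls)) {
    ag <- stats::aggregate(list(count = cnt),
                           by = list(type = typ, class = cls), FUN = sum)
    ag[order(ag$type, ag$class), ]
  } else data.frame(type = character(0), class = character(0),
                    count = integer(0))
  detectable <- if (nrow(J)) sum(J$count[J$class %in% detectable_junction_classes()]) else 0L
  structure(list(
    T5 = T5, T3 = T3, R = R, J = J,
    true_hr = if (min(T5, T3) > 0) R / min(T5, T3) else 0,
    true_concat = if (T5 + T3 > 0) detectable / (T5 + T3) else 0),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> T5=%d T3=%d R=%d true_hr=%.4f true_concat=%.4f (%d junction classes)\n",
              x$T5, x$T3, x$R, x$true_hr, x$true_concat, nrow(x$J)))
  invisible(x)
}

#' Simulate transcript counts
#'
#' Expression is driven by the promoter on the 5' vector; full-length
#' message requires the recombined transgene. `recombined ~
#' Poisson(expr_rate * R)`; premature 5'-vector leak transcripts `~
#' Poisson(leak_rate * free 5' units)` where free units are all 5' units
#' not consumed into HR molecules; aberrant 3' transcripts are zero
#' whenever the 3' construct lacks a promoter.
#'
#' @param pop a `sample_population`.
#' @param leak_rate transcripts per free 5' unit (small).
#' @param expr_rate transcripts per recombined molecule.
#' @param seed RNG seed.
#' @param three_rate transcripts per 3' unit; 0 for the default
#'   promoterless 3' construct.
#' @return object of class `transcript_population` (named counts).
#' @export
simulate_transcripts <- function(pop, leak_rate = 0.02, expr_rate = 2,
                                 seed = 1L, three_rate = 0) {
  stopifnot(leak_rate >= 0, expr_rate >= 0, three_rate >= 0)
  gt <- ground_truth_metrics(pop)
  set.seed(as.integer(seed))
  free5 <- gt$T5 - gt$R
  counts <- c(
    recombined = stats::rpois(1, expr_rate * gt$R),
    five_leak = stats::rpois(1, leak_rate * free5),
    three_aberrant = if (three_rate > 0) stats::rpois(1, three_rate * gt$T3) else 0L)
  structure(list(counts = counts), class = "transcript_population")
}

#' Write / read a species table
#'
#' TSV with columns `structure` (see [structure_string()]), `topology`,
#' `count`; host genome count is carried in a header comment line.
#'
#' @param pop a `sample_population`.
#' @param path output file.
#' @export
write_species_table <- function(pop, path) {
  df <- data.frame(
    structure = vapply(pop$species, structure_string, character(1)),
    topology = vapply(pop$species, `[[`, character(1), "topology"),
    count = vapply(pop$species, `[[`, integer(1), "count"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# host_genomes\t%d", pop$host_genomes), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  first <- readLines(path, n = 1L)
  hg <- if (startsWith(first, "# host_genomes"))
    as.integer(strsplit(first, "\t")[[1]][2]) else 0L
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sp <- mapply(parse_structure, df$structure, df$count,
               SIMPLIFY = FALSE, USE.NAMES = FALSE)
  sample_population(sp, host_genomes = hg)
}

#' Concatemer-fraction parameter for a target detectable junction fraction
#'
#' Closed-form calibration: under [sim_params()] expectations, the expected
#' assay-detectable junction fraction is
#' `phi * M/(T5+T3) * (1 - p) * d`, where `M` is the unit count remaining
#' after HR, `p` the chain-length geometric parameter and `d` the fraction
#' of junctions in detectable classes (all except same-identity
#' head-to-tail junctions). Solves for `phi`.
#'
#' @param target desired detectable junction fraction (e.g. 0.04).
#' @param p a [sim_params()] object supplying all other parameters.
#' @return phi value.
#' @export
phi_for_concat_target <- function(target, p) {
  stopifnot(inherits(p, "sim_params"), target >= 0)
  T5 <- p$u5 * p$host_genomes; T3 <- p$u3 * p$host_genomes
  R <- p$hr_fraction * min(T5, T3)
  n5 <- T5 - R; n3 <- T3 - R; M <- n5 + n3
  w <- p$orientation_weights
  # probability a junction is head-to-tail, averaged over free-end state;
  # under the chain recursion both end states give the renormalized forms
  pht <- mean(c(w[1] / (w[1] + w[3]), w[1] / (w[1] + w[2])))
  psame <- (n5^2 + n3^2) / (n5 + n3)^2
  d <- 1 - pht * psame
  denom <- (M / (T5 + T3)) * (1 - p$chain_length_p) * d
  if (denom <= 0) stop_dq("no junctions possible under these parameters", "sim_invalid")
  phi <- target / denom
  if (phi > 1) stop_dq("target junction fraction unreachable (phi > 1)", "sim_invalid")
  phi
}
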