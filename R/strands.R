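# Design and validation of DNA docking/imager strand pairs.
#
# Pairs are short (11-12 nt), AT-rich (GC 30-40%) exact reverse complements:
# long enough to hybridize stably during imaging, weak enough that a
# salt-concentration change (not heat) releases the imager strand during the
# wash. Panels must be mutually orthogonal so an imager strand only ever
# finds its own docking strand.

check_dna <- function(seq, what = "sequence") {
  if (!nzchar(seq)) stop2("empty %s", what)
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!ch %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop2("invalid character '%s' at position %d of %s", ch[bad[1]], bad[1],
          what)
  paste(ch, collapse = "")
}

#' Reverse complement of a DNA sequence
#' @param seq DNA string over A/C/G/T
#' @return reverse-complement string
#' @export
reverse_complement <- function(seq) {
  seq <- check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a DNA sequence
#' @param seq DNA string over A/C/G/T
#' @return `(#G + #C) / length`
#' @export
gc_fraction <- function(seq) {
  seq <- check_dna(seq)
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / length(ch)
}

# Unified nearest-neighbor parameters for DNA/DNA duplexes at 1 M NaCl
# (SantaLucia 1998, PNAS 95:1460): dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
INIT_GC <- c(dH = 0.1, dS = -2.8)   # duplex initiation with a terminal G/C
INIT_AT <- c(dH = 2.3, dS = 4.1)    # ... with a terminal A/T

#' Duplex melting temperature (nearest-neighbor model)
#'
#' Two-state nearest-neighbor thermodynamics with the unified DNA/DNA
#' parameter set (SantaLucia 1998) and the entropic monovalent-salt
#' correction `dS(Na+) = dS(1M) + 0.368 * N * ln([Na+])` with `N` the number
#' of stacked pairs. `Tm = 1000 * dH / (dS + R * ln(Ct / x)) - 273.15`, with
#' `x = 4` for non-self-complementary duplexes (1 for self-complementary).
#' Model metadata is attached as the `model` attribute.
#'
#' @param seq DNA string, length >= 8 (model validity floor for these short
#'   duplexes)
#' @param salt_mM monovalent cation concentration in mM
#' @param conc_nM total strand concentration in nM
#' @return Tm in degrees Celsius
#' @export
melting_temperature <- function(seq, salt_mM = 500, conc_nM = 500) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  if (n < 8) stop2("nearest-neighbor model needs length >= 8 (got %d)", n)
  if (salt_mM <= 0 || conc_nM <= 0) stop2("salt and strand concentration must be positive")
  ch <- strsplit(seq, "")[[1]]
  steps <- paste0(ch[-n], ch[-1])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in c(ch[1], ch[n])) {
    init <- if (term %in% c("G", "C")) INIT_GC else INIT_AT
    dH <- dH + init["dH"]; dS <- dS + init["dS"]
  }
  dS <- dS + 0.368 * (n - 1) * log(salt_mM / 1000)
  selfc <- identical(seq, reverse_complement(seq))
  x <- if (selfc) 1 else 4
  R <- 1.9872
  tm <- 1000 * dH / (dS + R * log(conc_nM * 1e-9 / x)) - 273.15
  attr(tm, "model") <- sprintf(
    "unified DNA/DNA NN (SantaLucia 1998) + 0.368*N*ln[Na+] salt entropy; Na+ %g mM, Ct %g nM",
    salt_mM, conc_nM)
  names(tm) <- NULL
  tm
}

#' Design constraints for docking/imager pairs
#'
#' Defaults follow the published optimum for salt-cycled imaging strands:
#' length 11-12 nt and GC fraction 0.30-0.40. The Tm window and buffer salt
#' are pipeline conventions (the source protocol cycles strands by salt
#' concentration but publishes no numeric Tm targets): 20-50 C at 500 mM
#' monovalent salt keeps duplexes bound in high-salt imaging buffer yet
#' releasable by a low-salt wash without heating.
#'
#' @param length_range integer `c(min, max)` strand length in nt
#' @param gc_range numeric `c(min, max)` GC fraction
#' @param tm_range numeric `c(min, max)` Tm window in Celsius
#' @param max_cross_complement_run longest tolerated complementary run (nt)
#'   between strands of different pairs
#' @param salt_mM monovalent salt for Tm evaluation
#' @param conc_nM strand concentration for Tm evaluation
#' @return a `design_constraints` list
#' @export
design_constraints <- function(length_range = c(11L, 12L),
                               gc_range = c(0.30, 0.40),
                               tm_range = c(20, 50),
                               max_cross_complement_run = 6L,
                               salt_mM = 500, conc_nM = 500) {
  stopifnot(length_range[1] <= length_range[2], gc_range[1] <= gc_range[2],
            tm_range[1] <= tm_range[2])
  structure(list(length_range = as.integer(length_range),
                 gc_range = gc_range, tm_range = tm_range,
                 max_cross_complement_run = as.integer(max_cross_complement_run),
                 salt_mM = salt_mM, conc_nM = conc_nM),
            class = "design_constraints")
}

#' Validate a docking/imager pair against design constraints
#'
#' Checks exact reverse-complementarity, length range, GC range and Tm
#' window, reporting every violated constraint.
#'
#' @param docking,imager DNA strings
#' @param constraints a [design_constraints()]
#' @return list: `pass` (logical), `reasons` (character vector drawn from
#'   "revcomp", "length", "gc", "tm"), `length`, `gc`, `tm`
#' @export
validate_imager_pair <- function(docking, imager,
                                 constraints = design_constraints()) {
  docking <- check_dna(docking, "docking strand")
  imager <- check_dna(imager, "imager strand")
  reasons <- character()
  if (!identical(imager, reverse_complement(docking)))
    reasons <- c(reasons, "revcomp")
  L <- nchar(docking)
  if (L < constraints$length_range[1] || L > constraints$length_range[2])
    reasons <- c(reasons, "length")
  gc <- gc_fraction(docking)
  if (gc < constraints$gc_range[1] - 1e-12 ||
      gc > constraints$gc_range[2] + 1e-12)
    reasons <- c(reasons, "gc")
  tm <- if (L >= 8)
    melting_temperature(docking, constraints$salt_mM, constraints$conc_nM)
  else NA_real_
  if (is.na(tm) || tm < constraints$tm_range[1] || tm > constraints$tm_range[2])
    reasons <- c(reasons, "tm")
  list(pass = length(reasons) == 0, reasons = reasons, length = L, gc = gc,
       tm = as.numeric(tm))
}

#' Longest complementary contiguous run between two strands
#'
#' The length of the longest contiguous stretch over which `a` can base-pair
#' with `b` in antiparallel orientation — i.e. the longest common substring
#' of `a` and the reverse complement of `b`.
#'
#' @param a,b DNA strings
#' @return integer run length
#' @export
longest_complementary_run <- function(a, b) {
  a <- check_dna(a); b <- check_dna(b)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(reverse_complement(b), "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match_j <- which(y == x[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Design a panel of mutually orthogonal docking/imager pairs
#'
#' Seeded rejection sampling: candidate docking strands are drawn with a GC
#' count inside the allowed range, checked against the length/GC/Tm
#' constraints, and accepted only if, for every already-accepted pair, the
#' longest complementary run between any strand of one pair and any strand
#' of the other does not exceed `max_cross_complement_run`. Deterministic
#' given the seed.
#'
#' @param n_pairs number of pairs to design
#' @param constraints a [design_constraints()]
#' @param seed RNG seed
#' @param fluorophores optional labels recycled over pairs
#' @param max_attempts search budget
#' @return data.frame: `name`, `docking`, `imager`, `length`, `gc`, `tm`,
#'   `fluorophore`
#' @export
design_orthogonal_panel <- function(n_pairs, constraints = design_constraints(),
                                    seed = 1L,
                                    fluorophores = c("AF594", "AF647"),
                                    max_attempts = 50000L) {
  stopifnot(n_pairs >= 0)
  if (n_pairs == 0)
    return(data.frame(name = character(), docking = character(),
                      imager = character(), length = integer(),
                      gc = numeric(), tm = numeric(),
                      fluorophore = character()))
  lens <- constraints$length_range[1]:constraints$length_range[2]
  gc_counts <- lapply(lens, function(L) {
    ks <- 0:L
    ks[ks / L >= constraints$gc_range[1] - 1e-12 &
       ks / L <= constraints$gc_range[2] + 1e-12]
  })
  if (all(lengths(gc_counts) == 0))
    stop2("infeasible constraints: no GC count satisfies the GC range")
  if (constraints$max_cross_complement_run < 1)
    stop2("infeasible constraints: any two strands share a complementary run of at least 1 nt")
  with_seed(seed, {
    accepted <- list()
    attempts <- 0L
    while (length(accepted) < n_pairs && attempts < max_attempts) {
      attempts <- attempts + 1L
      li <- sample(seq_along(lens), 1)
      L <- lens[li]
      if (!length(gc_counts[[li]])) next
      k <- if (length(gc_counts[[li]]) == 1) gc_counts[[li]]
           else sample(gc_counts[[li]], 1)
      pos <- sample(L, k)
      ch <- sample(c("A", "T"), L, replace = TRUE)
      ch[pos] <- sample(c("G", "C"), k, replace = TRUE)
      cand <- paste(ch, collapse = "")
      v <- validate_imager_pair(cand, reverse_complement(cand), constraints)
      if (!v$pass) next
      cand_im <- reverse_complement(cand)
      ok <- TRUE
      for (p in accepted) {
        run <- max(longest_complementary_run(cand, p$docking),
                   longest_complementary_run(cand, p$imager))
        if (run > constraints$max_cross_complement_run) { ok <- FALSE; break }
      }
      if (!ok) next
      accepted[[length(accepted) + 1]] <-
        list(docking = cand, imager = cand_im, length = v$length, gc = v$gc,
             tm = v$tm)
    }
    if (length(accepted) < n_pairs)
      stop2("search budget exhausted: found %d of %d orthogonal pairs",
            length(accepted), n_pairs)
    data.frame(
      name = sprintf("pair%02d", seq_len(n_pairs)),
      docking = vapply(accepted, `[[`, character(1), "docking"),
      imager = vapply(accepted, `[[`, character(1), "imager"),
      length = vapply(accepted, `[[`, integer(1), "length"),
      gc = vapply(accepted, `[[`, numeric(1), "gc"),
      tm = vapply(accepted, `[[`, numeric(1), "tm"),
      fluorophore = rep_len(fluorophores, n_pairs))
  })
}

#' Write a strand panel to FASTA
#'
#' Two records per pair (`<name>_docking`, `<name>_imager`); headers carry
#' the fluorophore and Tm.
#'
#' @param panel data.frame from [design_orthogonal_panel()]
#' @param path output FASTA path
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(c(rbind(panel$docking, panel$imager)))
  names(seqs) <- as.vector(rbind(
    sprintf("%s_docking fluorophore=%s tm=%.2f", panel$name, panel$fluorophore,
            panel$tm),
    sprintf("%s_imager fluorophore=%s tm=%.2f", panel$name, panel$fluorophore,
            panel$tm)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
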