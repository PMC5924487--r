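#' Default TFBS motif registry for the D5-style mini-promoter
#'
#' Ships the three binding-site elements used by the default construct:
#' the NF-kB site, the cAMP response element (CRE, bound by CREB) and
#' the hypoxia response element core (HRE, bound by HIF-1a). The
#' sequences are canonical consensus motifs from the literature, shipped
#' as documented stand-ins; the registry is the single source of truth
#' and is intended to be overridden with project-specific element
#' sequences.
#'
#' @return A data frame with columns `name`, `sequence`, `note`.
#' @export
default_motif_registry <- function() {
  data.frame(
    name = c("NFKB", "CRE", "HRE"),
    sequence = c("GGGACTTTCC", "TGACGTCA", "ACGTG"),
    note = c("NF-kB consensus site (kB motif)",
             "cAMP response element (CREB site)",
             "hypoxia response element core (HIF-1a site)"),
    stringsAsFactors = FALSE
  )
}

#' Restriction enzymes used for cloning checks
#'
#' @param name Enzyme label.
#' @param site DNA recognition sequence (A/C/G/T, length >= 4).
#' @return `restriction_enzyme()`: a `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, site) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("enzyme 'name' must be a non-empty string")
  }
  site <- toupper(site)
  if (!dna_alphabet_valid(site) || nchar(site) < 4L) {
    stopf("enzyme site must be A/C/G/T and at least 4 bases, got '%s'",
          site)
  }
  structure(list(name = name, site = site), class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @details `default_enzymes()` returns the four enzymes relevant to
#'   the default cloning scheme: MluI and ClaI (vector digestion for
#'   promoter insertion) and KpnI and BglII (primer tails for the
#'   transgene insert).
#' @return `default_enzymes()`: named list of `restriction_enzyme`
#'   objects.
#' @export
default_enzymes <- function() {
  list(
    MluI = restriction_enzyme("MluI", "ACGCGT"),
    ClaI = restriction_enzyme("ClaI", "ATCGAT"),
    KpnI = restriction_enzyme("KpnI", "GGTACC"),
    BglII = restriction_enzyme("BglII", "AGATCT")
  )
}

resolve_motif <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stopf("unknown motif name '%s' in registry", name)
  seq <- toupper(registry$sequence[i])
  if (!iupac_valid(seq) || !nzchar(seq)) {
    stopf("motif '%s' has an invalid sequence '%s'", name, seq)
  }
  if (!dna_alphabet_valid(seq)) {
    # degenerate IUPAC consensus: require a declared concrete expansion
    exp_col <- registry$expansion
    expansion <- if (!is.null(exp_col)) toupper(exp_col[i]) else NA_character_
    if (is.na(expansion) || !nzchar(expansion)) {
      stopf(paste0("motif '%s' is IUPAC-degenerate ('%s') and has no ",
                   "declared expansion"), name, seq)
    }
    if (!dna_alphabet_valid(expansion) ||
        nchar(expansion) != nchar(seq) ||
        !grepl(paste0("^", consensus_to_regex(seq), "$"), expansion)) {
      stopf("expansion '%s' does not match the consensus '%s' of motif '%s'",
            expansion, seq, name)
    }
    seq <- expansion
  }
  seq
}

consensus_to_regex <- function(consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(consensus, "")[[1L]]], collapse = "")
}

#' Assemble a multi-copy TFBS mini-promoter
#'
#' Concatenates, in the given motif order, the requested number of
#' consecutive copies of each binding-site element, joining consecutive
#' elements (including copies of the same motif) with the spacer. The
#' default reproduces the D5-style layout: three copies each of the
#' NF-kB site, the CRE and the HRE, in that order. Every copy is
#' recorded as a feature with 0-based half-open coordinates that slice
#' exactly its motif sequence out of the assembled promoter.
#'
#' @param registry Motif registry data frame (`name`, `sequence`,
#'   optional `expansion` for IUPAC-degenerate consensi, optional
#'   `note`).
#' @param order Ordered character vector of motif names.
#' @param copies Copies per motif: a single count or one per motif.
#' @param spacer DNA string inserted between consecutive elements
#'   (default empty).
#' @return An object of class `promoter_construct`: list with
#'   `elements`, `spacer`, `sequence`, `features` (data frame `name`,
#'   `start`, `end`, `strand`) and `length`.
#' @examples
#' d5 <- assemble_promoter(default_motif_registry())
#' d5$length
#' @export
assemble_promoter <- function(registry,
                              order = c("NFKB", "CRE", "HRE"),
                              copies = 3L,
                              spacer = "") {
  if (!is.data.frame(registry) ||
      !all(c("name", "sequence") %in% names(registry))) {
    stopf("'registry' must be a data frame with 'name' and 'sequence'")
  }
  if (anyDuplicated(registry$name)) stopf("registry names must be unique")
  if (!length(order)) stopf("'order' must name at least one motif")
  if (length(copies) == 1L) copies <- rep(copies, length(order))
  if (length(copies) != length(order)) {
    stopf("'copies' must be a single count or one per motif in 'order'")
  }
  copies <- vapply(copies, check_count, integer(1L), name = "copies")
  spacer <- toupper(spacer)
  if (!dna_alphabet_valid(spacer)) {
    stopf("'spacer' must be a (possibly empty) A/C/G/T string")
  }

  seqs <- vapply(order, resolve_motif, character(1L), registry = registry)
  parts <- character(0)
  elements <- data.frame(motif = character(0), copy = integer(0))
  for (i in seq_along(order)) {
    parts <- c(parts, rep(seqs[[i]], copies[i]))
    elements <- rbind(elements,
                      data.frame(motif = order[i],
                                 copy = seq_len(copies[i])))
  }
  n_el <- length(parts)
  sequence <- paste(parts, collapse = spacer)
  starts <- cumsum(c(0L, head(nchar(parts), -1L) + nchar(spacer)))
  features <- data.frame(
    name = elements$motif,
    start = starts,
    end = starts + nchar(parts),
    strand = "+",
    stringsAsFactors = FALSE
  )
  structure(list(
    elements = elements,
    spacer = spacer,
    sequence = sequence,
    features = features,
    length = nchar(sequence)
  ), class = "promoter_construct")
}

#' @export
print.promoter_construct <- function(x, ...) {
  cat(sprintf("promoter_construct: %d bp, %d elements (%s)\n",
              x$length, nrow(x$features),
              paste(unique(x$features$name), collapse = ", ")))
  cat(strwrap(x$sequence, width = 60), sep = "\n")
  invisible(x)
}

#' Scan a sequence for restriction-enzyme recognition sites
#'
#' Reports every exact occurrence of each enzyme's site on the given
#' strand, plus occurrences on the reverse complement mapped back to
#' forward-strand coordinates (digestion is strand-agnostic).
#' Palindromic sites are reported once per position. An empty result
#' means the sequence is clone-safe for those enzymes.
#'
#' @param sequence DNA string (may be empty).
#' @param enzymes List of [restriction_enzyme()] objects.
#' @return Data frame with columns `enzyme` and `offset` (0-based),
#'   sorted by offset; zero rows if no site occurs.
#' @export
scan_restriction_sites <- function(sequence, enzymes) {
  sequence <- toupper(sequence)
  if (!dna_alphabet_valid(sequence)) {
    stopf("'sequence' must be an A/C/G/T string")
  }
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  hits <- data.frame(enzyme = character(0), offset = integer(0))
  if (!nzchar(sequence)) return(hits)
  subject <- Biostrings::DNAString(sequence)
  for (enz in enzymes) {
    stopifnot(inherits(enz, "restriction_enzyme"))
    sites <- unique(c(enz$site, revcomp(enz$site)))
    offs <- integer(0)
    for (s in sites) {
      m <- Biostrings::matchPattern(s, subject)
      offs <- c(offs, BiocGenerics::start(m) - 1L)
    }
    offs <- sort(unique(offs))
    if (length(offs)) {
      hits <- rbind(hits, data.frame(enzyme = enz$name, offset = offs,
                                     stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$offset, hits$enzyme), ]
  rownames(hits) <- NULL
  hits
}

#' Design cloning primers with restriction-site tails
#'
#' Builds a forward/reverse primer pair for amplifying a target while
#' introducing restriction sites at both ends: the forward primer is
#' `prefix + forward site + first anneal_length bases of the target`;
#' the reverse primer is `prefix + reverse site + reverse complement of
#' the last anneal_length bases`. The short prefix gives the enzyme
#' footing to cut near the fragment end. A warning field lists any
#' enzyme whose site also occurs inside the target, since digestion
#' would then cut the insert itself.
#'
#' @param target Target DNA string to amplify.
#' @param enzyme_fw,enzyme_rv [restriction_enzyme()] objects for the 5'
#'   and 3' tails.
#' @param prefix DNA string prepended before each site (default
#'   `"AAA"`).
#' @param anneal_length Number of target bases each primer anneals to.
#' @return An object of class `primer_pair`: list with `forward`,
#'   `reverse`, `enzyme_fw`, `enzyme_rv`, `prefix`, `anneal_length`,
#'   `warnings` (character vector, possibly empty).
#' @examples
#' pr <- design_primers("TGAACTTTCTGCTGTCTTGGGATCGAA",
#'                      default_enzymes()$KpnI, default_enzymes()$BglII,
#'                      prefix = "AAA", anneal_length = 21)
#' pr$forward
#' @export
design_primers <- function(target, enzyme_fw, enzyme_rv,
                           prefix = "AAA", anneal_length = 21L) {
  target <- toupper(target)
  prefix <- toupper(prefix)
  if (!dna_alphabet_valid(target) || !nzchar(target)) {
    stopf("'target' must be a non-empty A/C/G/T string")
  }
  if (!dna_alphabet_valid(prefix)) {
    stopf("'prefix' must be a (possibly empty) A/C/G/T string")
  }
  stopifnot(inherits(enzyme_fw, "restriction_enzyme"),
            inherits(enzyme_rv, "restriction_enzyme"))
  anneal_length <- check_count(anneal_length, "anneal_length")
  if (anneal_length > nchar(target)) {
    stopf("'anneal_length' (%d) exceeds the target length (%d)",
          anneal_length, nchar(target))
  }
  fw_anneal <- substr(target, 1L, anneal_length)
  rv_anneal <- substr(target, nchar(target) - anneal_length + 1L,
                      nchar(target))
  warnings <- character(0)
  for (enz in list(enzyme_fw, enzyme_rv)) {
    if (nrow(scan_restriction_sites(target, list(enz)))) {
      warnings <- c(warnings, sprintf(
        "%s site (%s) occurs inside the target; digestion would cut the insert",
        enz$name, enz$site))
    }
  }
  structure(list(
    forward = paste0(prefix, enzyme_fw$site, fw_anneal),
    reverse = paste0(prefix, enzyme_rv$site, revcomp(rv_anneal)),
    enzyme_fw = enzyme_fw,
    enzyme_rv = enzyme_rv,
    prefix = prefix,
    anneal_length = anneal_length,
    warnings = warnings
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("forward (%s): 5'-%s-3'\n", x$enzyme_fw$name, x$forward))
  cat(sprintf("reverse (%s): 5'-%s-3'\n", x$enzyme_rv$name, x$reverse))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Write and read a promoter construct
#'
#' `write_construct()` emits two files from a path prefix: a FASTA
#' record of the sequence (wrapped at 60 columns) at `<path>.fasta` and
#' a tab-delimited feature table (`name`, `start`, `end`, `strand`;
#' 0-based half-open coordinates) at `<path>.features.tsv`.
#' `read_construct()` reverses the pair.
#'
#' @param construct A `promoter_construct`.
#' @param path Path prefix (extensions are appended).
#' @param name FASTA record name.
#' @return `write_construct()`: the two file paths, invisibly.
#'   `read_construct()`: a `promoter_construct` (with `elements`
#'   reconstructed from the feature table).
#' @export
write_construct <- function(construct, path, name = "mini_promoter") {
  stopifnot(inherits(construct, "promoter_construct"))
  fasta <- paste0(path, ".fasta")
  feats <- paste0(path, ".features.tsv")
  dna <- Biostrings::DNAStringSet(construct$sequence)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, fasta, width = 60L)
  utils::write.table(construct$features, feats, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, features = feats))
}

#' @rdname write_construct
#' @export
read_construct <- function(path) {
  fasta <- paste0(path, ".fasta")
  feats <- paste0(path, ".features.tsv")
  dna <- Biostrings::readDNAStringSet(fasta)
  features <- utils::read.delim(feats, stringsAsFactors = FALSE)
  sequence <- as.character(dna[[1L]])
  copy <- stats::ave(seq_len(nrow(features)), features$name,
                     FUN = seq_along)
  structure(list(
    elements = data.frame(motif = features$name, copy = copy),
    spacer = NA_character_,
    sequence = sequence,
    features = features,
    length = nchar(sequence)
  ), class = "promoter_construct")
}
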