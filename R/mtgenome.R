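# Human mtDNA gene model (rCRS / NC_012920 coordinates), vertebrate
# mitochondrial genetic code, and codon-level consequence annotation.

# Vertebrate mitochondrial code (NCBI transl_table=2).
# Deviations from the standard code: AGA/AGG -> STOP, ATA -> M, TGA -> W.
.mt_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.mt_genome_length <- 16569L

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(.complement[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Embedded rCRS mitochondrial gene model
#'
#' The 37 mtDNA genes plus the non-coding control region, with 1-based
#' inclusive rCRS (NC_012920) coordinates. The control region wraps the
#' replication origin and is represented by two rows (`CR`, segments
#' 16024-16569 and 1-576). Coordinates follow the MitoMap convention.
#'
#' @return A tibble with columns `name`, `start`, `end`, `strand`
#'   (`"heavy"`/`"light"`), `kind` (`protein`, `tRNA`, `rRNA`, `control`)
#'   and `complex_assignment` (`CI`, `CIII`, `CIV`, `CV` or `none`),
#'   ordered by `start`.
#' @export
#' @examples
#' mt_gene_model()
mt_gene_model <- function() {
  m <- tibble::tribble(
    ~name,      ~start,  ~end,    ~strand,  ~kind,     ~complex_assignment,
    "CR",       1L,      576L,    "heavy",  "control", "none",
    "MT-TF",    577L,    647L,    "heavy",  "tRNA",    "none",
    "MT-RNR1",  648L,    1601L,   "heavy",  "rRNA",    "none",
    "MT-TV",    1602L,   1670L,   "heavy",  "tRNA",    "none",
    "MT-RNR2",  1671L,   3229L,   "heavy",  "rRNA",    "none",
    "MT-TL1",   3230L,   3304L,   "heavy",  "tRNA",    "none",
    "MT-ND1",   3307L,   4262L,   "heavy",  "protein", "CI",
    "MT-TI",    4263L,   4331L,   "heavy",  "tRNA",    "none",
    "MT-TQ",    4329L,   4400L,   "light",  "tRNA",    "none",
    "MT-TM",    4402L,   4469L,   "heavy",  "tRNA",    "none",
    "MT-ND2",   4470L,   5511L,   "heavy",  "protein", "CI",
    "MT-TW",    5512L,   5579L,   "heavy",  "tRNA",    "none",
    "MT-TA",    5587L,   5655L,   "light",  "tRNA",    "none",
    "MT-TN",    5657L,   5729L,   "light",  "tRNA",    "none",
    "MT-TC",    5761L,   5826L,   "light",  "tRNA",    "none",
    "MT-TY",    5826L,   5891L,   "light",  "tRNA",    "none",
    "MT-CO1",   5904L,   7445L,   "heavy",  "protein", "CIV",
    "MT-TS1",   7446L,   7514L,   "light",  "tRNA",    "none",
    "MT-TD",    7518L,   7585L,   "heavy",  "tRNA",    "none",
    "MT-CO2",   7586L,   8269L,   "heavy",  "protein", "CIV",
    "MT-TK",    8295L,   8364L,   "heavy",  "tRNA",    "none",
    "MT-ATP8",  8366L,   8572L,   "heavy",  "protein", "CV",
    "MT-ATP6",  8527L,   9207L,   "heavy",  "protein", "CV",
    "MT-CO3",   9207L,   9990L,   "heavy",  "protein", "CIV",
    "MT-TG",    9991L,   10058L,  "heavy",  "tRNA",    "none",
    "MT-ND3",   10059L,  10404L,  "heavy",  "protein", "CI",
    "MT-TR",    10405L,  10469L,  "heavy",  "tRNA",    "none",
    "MT-ND4L",  10470L,  10766L,  "heavy",  "protein", "CI",
    "MT-ND4",   10760L,  12137L,  "heavy",  "protein", "CI",
    "MT-TH",    12138L,  12206L,  "heavy",  "tRNA",    "none",
    "MT-TS2",   12207L,  12265L,  "heavy",  "tRNA",    "none",
    "MT-TL2",   12266L,  12336L,  "heavy",  "tRNA",    "none",
    "MT-ND5",   12337L,  14148L,  "heavy",  "protein", "CI",
    "MT-ND6",   14149L,  14673L,  "light",  "protein", "CI",
    "MT-TE",    14674L,  14742L,  "light",  "tRNA",    "none",
    "MT-CYB",   14747L,  15887L,  "heavy",  "protein", "CIII",
    "MT-TT",    15888L,  15953L,  "heavy",  "tRNA",    "none",
    "MT-TP",    15956L,  16023L,  "light",  "tRNA",    "none",
    "CR",       16024L,  16569L,  "heavy",  "control", "none"
  )
  dplyr::arrange(m, .data$start)
}

#' Load a mitochondrial gene model
#'
#' Returns the embedded rCRS model, or parses a user-supplied TSV with the
#' same columns (`name`, `start`, `end`, `strand`, `kind`,
#' `complex_assignment`).
#'
#' @param source Optional path to a gene-model TSV. `NULL` (default)
#'   returns the embedded model.
#' @return A gene-model tibble ordered by `start` (see [mt_gene_model()]).
#' @export
load_gene_model <- function(source = NULL) {
  if (is.null(source)) {
    return(mt_gene_model())
  }
  m <- readr::read_tsv(source, show_col_types = FALSE,
                       col_types = readr::cols(
                         name = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         strand = readr::col_character(),
                         kind = readr::col_character(),
                         complex_assignment = readr::col_character()
                       ))
  required <- c("name", "start", "end", "strand", "kind", "complex_assignment")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("gene-model schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(m$start) | is.na(m$end) | m$start < 1L |
                 m$end > .mt_genome_length | m$end < m$start)
  if (length(bad) > 0) {
    stop("gene-model schema error at line ", bad[1] + 1L,
         ": require 1 <= start <= end <= ", .mt_genome_length, call. = FALSE)
  }
  bad_strand <- which(!m$strand %in% c("heavy", "light"))
  if (length(bad_strand) > 0) {
    stop("gene-model schema error at line ", bad_strand[1] + 1L,
         ": strand must be 'heavy' or 'light'", call. = FALSE)
  }
  bad_kind <- which(!m$kind %in% c("protein", "tRNA", "rRNA", "control"))
  if (length(bad_kind) > 0) {
    stop("gene-model schema error at line ", bad_kind[1] + 1L,
         ": kind must be protein/tRNA/rRNA/control", call. = FALSE)
  }
  dplyr::arrange(m, .data$start)
}

#' Translate a codon under the vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: `AGA`/`AGG` are stops, `ATA` codes for Met and
#' `TGA` for Trp. Vectorized.
#'
#' @param codon Character vector of 3-base DNA codons (A/C/G/T only).
#' @return Character vector of 1-letter amino acids, `"*"` for stop.
#' @export
#' @examples
#' mt_translate_codon(c("TGA", "AGA", "ATA"))
mt_translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) {
    stop("codons must be exactly 3 bases", call. = FALSE)
  }
  aa <- unname(.mt_code[codon])
  if (anyNA(aa)) {
    bad <- codon[is.na(aa)][1]
    stop("codon '", bad, "' contains an ambiguous or invalid base",
         call. = FALSE)
  }
  aa
}

# Translate a full coding-strand CDS string; no stop-at-terminator handling,
# the caller decides what to do with internal stops.
mt_translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  starts <- seq(1L, n, by = 3L)
  mt_translate_codon(substring(cds, starts, starts + 2L))
}

# ---- reference sequence ----------------------------------------------------

.oxshift_env <- new.env(parent = emptyenv())

#' Embedded mitochondrial reference sequence (synthetic stand-in)
#'
#' Returns the 16,569-base reference shipped with the package as a single
#' character string. The sequence is a deterministic *synthetic* stand-in
#' generated by [build_synthetic_reference()]: it uses the true rCRS gene
#' coordinates and valid vertebrate-mitochondrial open reading frames
#' (including the ATP8/ATP6 and ND4L/ND4 overlaps, incomplete stop codons
#' and the placeholder `N` at position 3107), but the bulk of the bases are
#' simulated, not the NC_012920 sequence. Coordinate-level results (gene
#' membership, codon indices, region classes) are exact; base-level results
#' reflect the synthetic sequence.
#'
#' @return A single uppercase string of length 16,569.
#' @export
mt_reference <- function() {
  if (is.null(.oxshift_env$reference)) {
    path <- system.file("extdata", "synthetic_rcrs.fa", package = "oxshift",
                        mustWork = TRUE)
    lines <- readLines(path)
    seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
    seq <- toupper(seq)
    if (nchar(seq) != .mt_genome_length) {
      stop("embedded reference has length ", nchar(seq),
           ", expected ", .mt_genome_length, call. = FALSE)
    }
    .oxshift_env$reference <- seq
  }
  .oxshift_env$reference
}

# Coding-strand CDS of a protein gene, with the incomplete terminal stop
# completed by polyadenylation A's so the CDS is a whole number of codons.
mt_cds <- function(gene, genome = mt_reference(), model = mt_gene_model()) {
  row <- model[model$name == gene & model$kind == "protein", ]
  if (nrow(row) != 1L) {
    stop("'", gene, "' is not a protein gene in the model", call. = FALSE)
  }
  s <- substr(genome, row$start, row$end)
  if (row$strand == "light") s <- revcomp(s)
  pad <- (3L - nchar(s) %% 3L) %% 3L
  paste0(s, strrep("A", pad))
}

#' Annotate mitochondrial single-nucleotide variants
#'
#' Assigns each variant to every overlapping gene of the rCRS model and, for
#' protein genes, computes the affected codon and amino-acid change under
#' the vertebrate mitochondrial genetic code. Light-strand genes (MT-ND6 and
#' several tRNAs) are annotated on the coding strand, i.e. with the
#' complemented alleles. Positions outside every gene are classified as
#' `control_region` (16024-16569 and 1-576) or `noncoding`.
#'
#' @param pos Integer vector of 1-based rCRS positions.
#' @param ref,alt Single reference/alternative bases (character vectors,
#'   recycled against `pos`). `ref` must match the embedded reference;
#'   multi-base alleles (indels) are rejected.
#' @param model Gene model tibble, default [mt_gene_model()].
#' @param genome Reference sequence string, default [mt_reference()].
#' @return A tibble with one row per (variant, overlapped gene):
#'   `pos`, `ref`, `alt`, `gene`, `kind`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `synonymy` (one of `synonymous`, `non_synonymous`, `tRNA`, `rRNA`,
#'   `control_region`, `noncoding`).
#' @export
#' @examples
#' \dontrun{
#' mt_annotate_variant(11991, "T", "C")
#' }
mt_annotate_variant <- function(pos, ref, alt, model = mt_gene_model(),
                                genome = mt_reference()) {
  n <- length(pos)
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  pos <- as.integer(pos)
  if (any(is.na(pos) | pos < 1L | pos > .mt_genome_length)) {
    stop("positions must lie in 1..", .mt_genome_length, call. = FALSE)
  }
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    i <- which(nchar(ref) != 1L | nchar(alt) != 1L)[1]
    stop("unsupported variant at position ", pos[i],
         ": only single-nucleotide variants are handled", call. = FALSE)
  }
  if (any(!ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A/C/G/T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ", call. = FALSE)
  }
  expected <- substring(genome, pos, pos)
  bad <- which(expected != ref)
  if (length(bad) > 0) {
    i <- bad[1]
    stop("reference mismatch at position ", pos[i], ": expected '",
         expected[i], "', got '", ref[i], "'", call. = FALSE)
  }

  annotate_one <- function(p, r, a) {
    hits <- model[model$start <= p & model$end >= p, ]
    if (nrow(hits) == 0L) {
      return(tibble::tibble(
        pos = p, ref = r, alt = a, gene = NA_character_, kind = "noncoding",
        codon_index = NA_integer_, ref_aa = NA_character_,
        alt_aa = NA_character_, synonymy = "noncoding"
      ))
    }
    purrr::pmap_dfr(hits, function(name, start, end, strand, kind,
                                   complex_assignment) {
      if (kind != "protein") {
        syn <- switch(kind, control = "control_region", kind)
        return(tibble::tibble(
          pos = p, ref = r, alt = a, gene = if (kind == "control") NA_character_ else name,
          kind = kind, codon_index = NA_integer_, ref_aa = NA_character_,
          alt_aa = NA_character_, synonymy = syn
        ))
      }
      if (strand == "heavy") {
        offset <- p - start + 1L
        r_c <- r
        a_c <- a
      } else {
        offset <- end - p + 1L
        r_c <- unname(.complement[r])
        a_c <- unname(.complement[a])
      }
      cds <- mt_cds(name, genome, model)
      ci <- as.integer(ceiling(offset / 3))
      within <- offset - 3L * (ci - 1L)
      codon <- substr(cds, 3L * ci - 2L, 3L * ci)
      stopifnot(substr(codon, within, within) == r_c)
      alt_codon <- codon
      substr(alt_codon, within, within) <- a_c
      ref_aa <- mt_translate_codon(codon)
      alt_aa <- mt_translate_codon(alt_codon)
      tibble::tibble(
        pos = p, ref = r, alt = a, gene = name, kind = "protein",
        codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa,
        synonymy = if (ref_aa == alt_aa) "synonymous" else "non_synonymous"
      )
    })
  }

  purrr::pmap_dfr(list(pos, ref, alt), annotate_one)
}

# ---- synthetic reference generation ---------------------------------------

# Codon pool of sense codons (no AGA/AGG/TAA/TAG).
.sense_codons <- names(.mt_code)[.mt_code != "*"]

#' Build the synthetic stand-in reference sequence
#'
#' Deterministically simulates a 16,569-base mitochondrial genome on the
#' real rCRS gene coordinates: every protein gene is a valid vertebrate-mito
#' ORF (ATG start, no internal stops in any overlapping frame, terminal TAA
#' or an incomplete T/TA stop where the real gene uses polyadenylation
#' completion), position 3107 is `N`, and a handful of codons are pinned so
#' that documented example substitutions (e.g. MT-ND4 F411S for 11991 T>C)
#' have the published amino-acid chemistry. This is the generator of the
#' FASTA shipped in `inst/extdata/synthetic_rcrs.fa`; it is *not* the
#' NC_012920 sequence.
#'
#' @param seed Integer seed; the default is the one used to build the
#'   shipped FASTA.
#' @param max_tries Resampling attempts for the overlapping-frame constraint.
#' @return A single uppercase string of length 16,569.
#' @export
build_synthetic_reference <- function(seed = 20200320L, max_tries = 200L) {
  model <- mt_gene_model()
  pins <- c(
    # MT-ND4 start codon (also fixes part of the ND4L overlap)
    "10760" = "A", "10761" = "T", "10762" = "G",
    # MT-ATP6 start codon inside MT-ATP8
    "8527" = "A", "8528" = "T", "8529" = "G",
    # worked-example codons: ND4 F411 (TTC), ND5 T387 (ACC), ND4L S28 (TCC)
    "11990" = "T", "11991" = "T", "11992" = "C",
    "13495" = "A", "13496" = "C", "13497" = "C",
    "10551" = "T", "10552" = "C", "10553" = "C",
    # MT-TP example base
    "15995" = "G"
  )
  pin_pos <- as.integer(names(pins))

  gen_once <- function() {
    g <- sample(c("A", "C", "G", "T"), .mt_genome_length, replace = TRUE)
    g[pin_pos] <- unname(pins)
    prot <- model[model$kind == "protein", ]
    for (i in seq_len(nrow(prot))) {
      start <- prot$start[i]; end <- prot$end[i]; strand <- prot$strand[i]
      len <- end - start + 1L
      n_full <- len %/% 3L
      rem <- len %% 3L
      # coding-strand position k (1-based) -> heavy-strand genome index
      idx <- function(k) if (strand == "heavy") start + k - 1L else end - k + 1L
      coding_pin <- function(k) {
        gi <- idx(k)
        if (gi %in% pin_pos || .already[gi]) {
          b <- g[gi]
          if (strand == "light") b <- unname(.complement[b])
          b
        } else {
          NA_character_
        }
      }
      put <- function(k, base) {
        gi <- idx(k)
        if (strand == "light") base <- unname(.complement[base])
        g[gi] <<- base
        .already[gi] <<- TRUE
      }
      for (ci in seq_len(n_full)) {
        ks <- (3L * ci - 2L):(3L * ci)
        fixed <- vapply(ks, coding_pin, character(1))
        if (ci == 1L) {
          cand <- "ATG"
        } else if (ci == n_full && rem == 0L) {
          cand <- "TAA"
        } else {
          cand <- .sense_codons
        }
        keep <- vapply(cand, function(cd) {
          all(is.na(fixed) | strsplit(cd, "")[[1]] == fixed)
        }, logical(1))
        cand <- cand[keep]
        if (length(cand) == 0L) {
          stop("pin conflict in ", prot$name[i], " codon ", ci, call. = FALSE)
        }
        codon <- if (length(cand) == 1L) cand else sample(cand, 1L)
        cb <- strsplit(codon, "")[[1]]
        for (j in 1:3) if (is.na(fixed[j])) put(ks[j], cb[j])
      }
      if (rem > 0L) {
        # incomplete stop: T or TA on the coding strand
        tail_bases <- if (rem == 1L) "T" else c("T", "A")
        for (j in seq_len(rem)) {
          k <- 3L * n_full + j
          if (is.na(coding_pin(k))) put(k, tail_bases[j])
        }
      }
    }
    g[3107L] <- "N"
    paste(g, collapse = "")
  }

  check <- function(seq) {
    prot <- model[model$kind == "protein", ]
    for (i in seq_len(nrow(prot))) {
      aa <- mt_translate_cds(mt_cds(prot$name[i], seq, model))
      body <- aa[-length(aa)]
      last <- aa[length(aa)]
      if (aa[1] != "M" || any(body == "*") || last != "*") return(FALSE)
    }
    TRUE
  }

  result <- withr::with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_tries)) {
      .already <- rep(FALSE, .mt_genome_length)
      seq <- tryCatch(gen_once(), error = function(e) NULL)
      if (!is.null(seq) && check(seq)) {
        out <- seq
        break
      }
    }
    out
  })
  if (is.null(result)) {
    stop("failed to generate a consistent synthetic reference in ",
         max_tries, " tries", call. = FALSE)
  }
  result
}

# ---- exports of the gene model ---------------------------------------------

#' Export the gene model as BED or GFF3
#'
#' BED uses 0-based half-open coordinates (`start - 1`, `end`); GFF3 keeps
#' the 1-based inclusive rCRS coordinates.
#'
#' @param model Gene model tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gene_model_to_bed <- function(model = mt_gene_model(), path) {
  bed <- tibble::tibble(
    chrom = "chrM",
    chromStart = model$start - 1L,
    chromEnd = model$end,
    name = model$name,
    score = 0L,
    strand = ifelse(model$strand == "heavy", "+", "-")
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname gene_model_to_bed
#' @export
gene_model_to_gff3 <- function(model = mt_gene_model(), path) {
  type <- dplyr::recode(model$kind, protein = "gene", tRNA = "tRNA_gene",
                        rRNA = "rRNA_gene", control = "region")
  lines <- c(
    "##gff-version 3",
    sprintf("chrM\toxshift\t%s\t%d\t%d\t.\t%s\t.\tID=%s;complex=%s",
            type, model$start, model$end,
            ifelse(model$strand == "heavy", "+", "-"),
            model$name, model$complex_assignment)
  )
  writeLines(lines, path)
  invisible(path)
}
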