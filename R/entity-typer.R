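#' @title Semantic typing of noun phrases
#' @description
#' Noun phrases are typed from two sources: pre-annotated entity
#' mentions (gene/gene-product mentions are assumed given, as in the
#' BioNLP-ST GE setting) and a head-noun/suffix lexicon for everything
#' else. Pre-annotated mentions are authoritative and are never
#' re-typed; the heuristic lexicon compares the head noun and its suffix
#' against per-type keyword lists ("locus" and "promoter" name gene
#' parts, "-ase" and "-in" suffixes suggest proteins, and so on).
#' @name entity_typer
NULL

new_entity_mention <- function(span, text, sem_type, source = "heuristic",
                               id = NA_character_) {
  stopifnot(span[2] > span[1])
  structure(list(span = as.integer(span), text = text, sem_type = sem_type,
                 source = source, id = id),
            class = "entity_mention")
}

#' @export
print.entity_mention <- function(x, ...) {
  cat("<mention> '", x$text, "' [", x$span[1], ",", x$span[2], ") ",
      x$sem_type, " (", x$source, ")\n", sep = "")
  invisible(x)
}

# head-noun keyword lexicon; a packaged reconstruction, editable via the
# lexicon argument of type_np
.head_lexicon <- list(
  gene_part = c("locus", "loci", "promoter", "promoters", "enhancer",
                "enhancers", "exon", "exons", "intron", "introns"),
  protein_part = c("domain", "domains", "residue", "residues", "site",
                   "sites", "subunit", "subunits", "terminus", "termini",
                   "motif", "motifs", "region", "regions", "fragment",
                   "fragments"),
  protein = c("protein", "proteins", "kinase", "kinases", "factor",
              "factors", "glycoprotein", "glycoproteins", "receptor",
              "receptors", "enzyme", "enzymes", "cytokine", "cytokines",
              "molecule", "molecules", "phosphatase", "phosphatases",
              "ligand", "ligands", "antibody", "antibodies"),
  rna = c("mRNA", "mRNAs", "transcript", "transcripts", "rRNA", "tRNA",
          "miRNA", "RNA", "RNAs"),
  class_noun = c("gene", "genes"),
  chemical = c("inhibitor", "inhibitors", "compound", "compounds", "drug",
               "drugs")
)

.protein_suffix_re <- "(ase|in)$"

#' Assign a semantic type to a noun phrase
#'
#' If the head token of the noun phrase overlaps a pre-annotated
#' mention, that mention is returned unchanged. Otherwise the head noun
#' is looked up in the keyword lexicon and typed by keyword or by suffix
#' (`-ase`, `-in` suggest proteins); anything else is `other`.
#'
#' @param np a `parse_tree` NP node (or a nominal preterminal/leaf), with
#'   spans in the same coordinate system as `preannotated`
#' @param preannotated list of `entity_mention` with `source =
#'   "preannotated"`
#' @param lexicon head-noun keyword lists; defaults to the packaged one
#' @return an `entity_mention` (either a pre-annotated one, or a
#'   heuristic mention covering the noun phrase)
#' @export
type_np <- function(np, preannotated = list(), lexicon = .head_lexicon) {
  idx <- if (inherits(np, "parse_tree")) tree_index(np) else np
  h <- np_head_leaf(idx, 1L)
  if (is.na(h)) h <- idx$leaves[length(idx$leaves)]
  hspan <- c(idx$start[h], idx$end[h])
  for (m in preannotated) {
    if (spans_overlap(hspan, m$span)) return(m)
  }
  head_tok <- idx$token[h]
  ty <- head_lookup(head_tok, lexicon)
  new_entity_mention(c(idx$start[1L], idx$end[1L]), idx_yield(idx, 1L), ty,
                     source = "heuristic")
}

head_lookup <- function(tok, lexicon = .head_lexicon) {
  for (ty in names(lexicon)) {
    if (tok %in% lexicon[[ty]] || tolower(tok) %in% tolower(lexicon[[ty]])) {
      return(ty)
    }
  }
  if (grepl(.protein_suffix_re, tok) && nchar(tok) > 4L &&
      tok == tolower(tok)) {
    return("protein")
  }
  "other"
}

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

# GGP is the unspecific gene-or-gene-product class: it subsumes gene,
# rna and protein, and an unspecific GGP mention satisfies any of them
.ggp_members <- c("gene", "rna", "protein")

#' Check a mention against an argument slot's type constraint
#'
#' True when the mention's semantic type is allowed by the slot, under
#' the GGP subsumption rule: a slot that allows `GGP` accepts `gene`,
#' `rna` and `protein` mentions, and an (unspecific) `GGP` mention
#' satisfies slots that ask for any of those finer types.
#'
#' @param mention an `entity_mention`
#' @param slot an `arg_slot`
#' @return logical
#' @export
satisfies <- function(mention, slot) {
  ty <- mention$sem_type
  allowed <- slot$allowed_types
  if (ty %in% allowed) return(TRUE)
  if ("GGP" %in% allowed && ty %in% .ggp_members) return(TRUE)
  if (ty == "GGP" && any(.ggp_members %in% allowed)) return(TRUE)
  FALSE
}

#' Read a BioNLP-ST .a1 entity file
#'
#' Parses lines of the form `T1<TAB>Protein 0 5<TAB>JNK` into
#' pre-annotated entity mentions. `Protein` annotations are mapped to
#' the GGP class.
#'
#' @param lines character vector of .a1 lines (or a single string)
#' @return list of `entity_mention` with `source = "preannotated"`
#' @export
read_a1 <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed .a1 line: ", ln)
    ann <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    ty <- if (ann[1] == "Protein") "GGP" else ann[1]
    out[[length(out) + 1L]] <- new_entity_mention(
      span = c(as.integer(ann[2]), as.integer(ann[3])),
      text = if (length(f) >= 3L) f[3] else "",
      sem_type = ty, source = "preannotated", id = f[1])
  }
  out
}
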