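## Gene Ontology handling: OBO parsing, ancestor closures, information
## content and Lin term similarity over an annotation corpus.

.computeAncestors <- function(terms, parents) {
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- integer(length(terms))  # 0 unvisited, 1 in progress, 2 done
  names(state) <- terms
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("cycle detected in ontology at term ", t)
    state[[t]] <<- 1L
    out <- t
    for (p in parents[[t]]) out <- union(out, visit(p))
    state[[t]] <<- 2L
    anc[[t]] <<- out
    out
  }
  for (t in terms) visit(t)
  anc
}

.newGoDag <- function(terms, termNames, parents, namespace) {
  roots <- terms[lengths(parents) == 0L]
  ancestors <- .computeAncestors(terms, parents)
  methods::new("GoDag", terms = terms, termNames = termNames,
               parents = parents, ancestors = ancestors,
               roots = roots, namespace = namespace)
}

#' Read a GO ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeps `is_a` edges (and `part_of` relationships
#' when requested), drops obsolete terms, and restricts the graph to one
#' namespace. Edges pointing outside the namespace are dropped with the
#' foreign term.
#'
#' @param path OBO file path.
#' @param namespace namespace to keep (default `"biological_process"`).
#' @param includePartOf also treat `relationship: part_of` as a parent edge
#'   (default `FALSE`).
#' @return a [GoDag-class].
#' @export
loadObo <- function(path, namespace = "biological_process",
                    includePartOf = FALSE) {
  lines <- readLines(path)
  stanzaStarts <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  if (!length(termStarts)) stop("no [Term] stanzas found in ", path)
  ends <- c(stanzaStarts[-1L] - 1L, length(lines))
  names(ends) <- stanzaStarts
  id <- character(); nm <- character(); ns <- character()
  parents <- list()
  for (s in termStarts) {
    block <- lines[(s + 1L):ends[[as.character(s)]]]
    getField <- function(f) sub(paste0("^", f, ":\\s*"), "",
                                grep(paste0("^", f, ":"), block, value = TRUE))
    if (length(grep("^is_obsolete:\\s*true", block))) next
    tid <- getField("id")[1L]
    if (is.na(tid)) next
    tns <- getField("namespace")[1L]
    tname <- getField("name")[1L]
    isa <- sub("\\s*!.*$", "", getField("is_a"))
    if (includePartOf) {
      rel <- getField("relationship")
      po <- sub("\\s*!.*$", "",
                sub("^part_of\\s+", "", grep("^part_of\\s", rel, value = TRUE)))
      isa <- c(isa, po)
    }
    id <- c(id, tid)
    nm <- c(nm, if (is.na(tname)) tid else tname)
    ns <- c(ns, if (is.na(tns)) NA_character_ else tns)
    parents[[tid]] <- isa
  }
  if (anyDuplicated(id)) stop("duplicate term id(s) in OBO file")
  known <- id
  unknown <- setdiff(unique(unlist(parents, use.names = FALSE)), known)
  if (length(unknown))
    stop("unknown parent term id(s): ", paste(unknown, collapse = ", "))
  keep <- is.na(ns) | ns == namespace
  keep[is.na(ns)] <- length(unique(stats::na.omit(ns))) <= 1L
  id <- id[keep]
  parents <- lapply(parents[id], function(p) intersect(p, id))
  names(parents) <- id
  dag <- .newGoDag(terms = id, termNames = stats::setNames(nm[keep], id),
                   parents = parents, namespace = namespace)
  methods::validObject(dag)
  dag
}

#' Write a [GoDag-class] as an OBO 1.2 file
#' @param dag a GoDag.
#' @param path output file.
#' @export
writeObo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag@terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", dag@termNames[[t]]),
             paste0("namespace: ", dag@namespace),
             paste0("is_a: ", dag@parents[[t]], recycle0 = TRUE), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build an annotation corpus from gene-term tables
#'
#' Merges one or more two-column (gene, term) tables, de-duplicates, drops
#' terms absent from the DAG with a warning, and propagates each gene's
#' annotations to all ancestor terms before counting distinct genes per
#' term.
#'
#' @param pairs a data.frame with columns gene and term, a list of such
#'   data.frames, or a character vector of TSV file paths (no header
#'   required; lines starting with `#` are skipped).
#' @param dag a [GoDag-class].
#' @return an [AnnotationCorpus-class].
#' @export
annotationCorpus <- function(pairs, dag) {
  readOne <- function(p) {
    if (is.character(p))
      p <- utils::read.table(p, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#",
                             col.names = c("gene", "term"))
    data.frame(gene = as.character(p[[1L]]), term = as.character(p[[2L]]),
               stringsAsFactors = FALSE)
  }
  if (is.data.frame(pairs)) pairs <- list(pairs)
  tab <- unique(do.call(rbind, lapply(pairs, readOne)))
  bad <- !(tab$term %in% dag@terms)
  if (any(bad)) {
    warning(sum(bad), " annotation(s) to terms absent from the DAG dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no usable annotations after merging")
  gene2terms <- split(tab$term, tab$gene)
  gene2terms <- lapply(gene2terms, unique)
  # propagate to ancestors, then invert
  propagated <- lapply(gene2terms, function(ts) {
    unique(unlist(dag@ancestors[ts], use.names = FALSE))
  })
  genes <- rep(names(propagated), lengths(propagated))
  terms <- unlist(propagated, use.names = FALSE)
  term2genes <- split(genes, terms)
  corpus <- methods::new("AnnotationCorpus",
                         gene2terms = gene2terms,
                         term2genes = term2genes,
                         termCounts = vapply(term2genes, length, integer(1)),
                         totalGenes = length(gene2terms))
  methods::validObject(corpus)
  corpus
}

#' Read a GAF 2.x annotation file as (gene, term) pairs
#'
#' Uses column 2 (gene identifier) and column 5 (GO ID), optionally
#' filtered by the aspect column (9): `P` for biological_process.
#'
#' @param path GAF file path (lines starting with `!` are comments).
#' @param aspect single aspect letter to keep, or `NULL` for all.
#' @return data.frame with columns gene and term.
#' @export
readGaf <- function(path, aspect = "P") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) {
    length(f) >= 9L && (is.null(aspect) || f[9L] == aspect)
  }, logical(1))
  fields <- fields[keep]
  data.frame(gene = vapply(fields, `[[`, character(1), 2L),
             term = vapply(fields, `[[`, character(1), 5L),
             stringsAsFactors = FALSE)
}

#' Annotation probability of a term
#'
#' `p(t)`: propagated gene count of `t` over the number of annotated genes.
#'
#' @param term term id.
#' @param corpus an [AnnotationCorpus-class].
#' @return probability in (0, 1\].
#' @export
termProb <- function(term, corpus) {
  cnt <- corpus@termCounts[term]
  if (is.na(cnt)) stop("term ", term, " has no annotations in the corpus")
  unname(cnt / corpus@totalGenes)
}

#' Information content of a term
#' @inheritParams termProb
#' @return `-log(p(t))`, >= 0.
#' @export
infoContent <- function(term, corpus) -log(termProb(term, corpus))

#' Lin semantic similarity between two GO terms
#'
#' Over the shared ancestors of the two terms (each term counted among its
#' own ancestors), the most informative common ancestor (MICA, smallest
#' annotation probability) is selected and the similarity is
#' `2 * log p(MICA) / (log p(t1) + log p(t2))`, in \[0, 1\]. Identical terms
#' score 1 (when `p < 1`); term pairs whose only shared ancestor is
#' uninformative (`p = 1`, the root) score 0.
#'
#' @param t1,t2 term ids present in the corpus.
#' @param dag a [GoDag-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param literal if `TRUE`, selects the ancestor maximizing `log p(t)`
#'   instead of minimizing it; since the root (`p = 1`) is a shared
#'   ancestor of every pair this variant is identically 0 and exists only
#'   to audit the alternative reading of the published formula.
#' @return similarity in \[0, 1\].
#' @export
linSimilarity <- function(t1, t2, dag, corpus, literal = FALSE) {
  p1 <- termProb(t1, corpus)
  p2 <- termProb(t2, corpus)
  if (!literal && t1 == t2) return(if (p1 < 1) 1 else 0)
  common <- intersect(dag@ancestors[[t1]], dag@ancestors[[t2]])
  common <- common[common %in% names(corpus@termCounts)]
  if (!length(common)) return(0)
  pc <- vapply(common, termProb, numeric(1), corpus = corpus)
  pm <- if (literal) max(pc) else min(pc)
  den <- log(p1) + log(p2)
  if (pm >= 1 || den == 0) return(0)
  min(1, max(0, 2 * log(pm) / den))
}
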