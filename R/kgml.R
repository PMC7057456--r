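#' Read a pathway graph from a KEGG KGML file
#'
#' Parses the KEGG Markup Language XML encoding of a pathway and builds the
#' signed gene-regulation network. Relation subtypes `activation` and
#' `expression` map to sign `+1`; `inhibition` and `repression` map to `-1`.
#' Entries of type `gene` become single nodes named by their first KEGG gene
#' id (the remaining ids and the graphics label are kept as display
#' metadata); entries of type `group` are expanded to their component gene
#' entries, so a relation touching a group yields one edge per member.
#' Relations carrying none of the signed subtypes (e.g.
#' `binding/association`) are skipped and counted in the load report
#' attached as attribute `kgml_report`.
#'
#' KEGG annotates some edges with subtypes such as `phosphorylation` or
#' `indirect effect` only; whether those represent signed regulation is
#' pathway-dependent, so they are excluded by default and can be opted in
#' through `include_subtypes`.
#'
#' @param path KGML file path.
#' @param name pathway name; defaults to the document's `title` (or `name`)
#'   attribute.
#' @param include_subtypes optional named integer vector mapping additional
#'   relation subtype names to signs, e.g. `c(phosphorylation = 1L)`.
#' @return A [pathway_graph()] with attribute `kgml_report`, a list with
#'   counts of total, used, skipped and conflicting relations.
#' @export
load_kgml <- function(path, name = NULL, include_subtypes = NULL) {
  doc <- xml2::read_xml(path)  # malformed XML errors here
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop(sprintf("%s: not a KGML document (no <pathway> root)",
                                path), call. = FALSE)
  if (is.null(name)) {
    name <- xml2::xml_attr(doc, "title")
    if (is.na(name) || !nzchar(name)) name <- xml2::xml_attr(doc, "name")
    if (is.na(name) || !nzchar(name)) name <- basename(path)
  }

  sign_map <- c(activation = 1L, expression = 1L,
                inhibition = -1L, repression = -1L)
  if (!is.null(include_subtypes)) {
    stopifnot(!is.null(names(include_subtypes)),
              all(include_subtypes %in% c(1L, -1L)))
    sign_map <- c(sign_map, include_subtypes)
  }

  entries <- xml2::xml_find_all(doc, "//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")

  # gene entries: first KEGG id is canonical, full list kept for display
  genes <- list()
  display <- character()
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      ids <- strsplit(trimws(xml2::xml_attr(entries[[i]], "name")),
                      "\\s+")[[1L]]
      ids <- ids[nzchar(ids)]
      if (length(ids) == 0L) next
      canon <- toupper(ids[1L])
      genes[[entry_id[i]]] <- canon
      gr <- xml2::xml_find_first(entries[[i]], "graphics")
      lab <- if (!is.na(gr)) xml2::xml_attr(gr, "name") else NA_character_
      display[canon] <- if (!is.na(lab)) lab else paste(ids, collapse = " ")
    }
  }
  # group entries expand to their member gene entries
  members <- list()
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_find_all(entries[[i]], "component")
      ids <- xml2::xml_attr(comp, "id")
      members[[entry_id[i]]] <- unlist(genes[ids], use.names = FALSE)
    }
  }
  resolve <- function(id) {
    if (!is.null(genes[[id]])) return(genes[[id]])
    if (!is.null(members[[id]])) return(members[[id]])
    NULL  # compound/map/other entry types are unsupported
  }

  relations <- xml2::xml_find_all(doc, "//relation")
  src <- character(); tgt <- character(); sgn <- integer()
  n_skipped <- 0L; skipped_subtypes <- character(); n_selfloop <- 0L
  for (rel in relations) {
    subs <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    sign <- sign_map[subs]
    sign <- sign[!is.na(sign)]
    if (length(sign) == 0L) {
      n_skipped <- n_skipped + 1L
      skipped_subtypes <- c(skipped_subtypes,
                            if (length(subs)) subs else "<none>")
      next
    }
    sign <- sign[[1L]]
    a <- resolve(xml2::xml_attr(rel, "entry1"))
    b <- resolve(xml2::xml_attr(rel, "entry2"))
    if (is.null(a) || is.null(b)) {
      n_skipped <- n_skipped + 1L
      skipped_subtypes <- c(skipped_subtypes, "<non-gene endpoint>")
      next
    }
    for (x in a) for (y in b) {
      if (x == y) { n_selfloop <- n_selfloop + 1L; next }
      src <- c(src, x); tgt <- c(tgt, y); sgn <- c(sgn, sign)
    }
  }

  # keep the first signed occurrence of each gene pair; conflicting duplicate
  # signs do occur in curated KEGG files and are reported, not fatal
  n_conflict <- 0L
  if (length(src)) {
    key <- paste(src, tgt, sep = "\r")
    keep <- !duplicated(key)
    first_sign <- sgn[match(key, key)]
    n_conflict <- sum(sgn != first_sign)
    src <- src[keep]; tgt <- tgt[keep]; sgn <- sgn[keep]
    if (n_conflict > 0L) {
      warning(sprintf("%s: %d relation(s) with conflicting signs; first occurrence kept",
                      path, n_conflict), call. = FALSE)
    }
  }
  if (length(src) == 0L) {
    warning(sprintf("%s: no signed relations found; returning an empty graph",
                    path), call. = FALSE)
  }

  g <- pathway_graph(data.frame(source = src, target = tgt, sign = sgn,
                                stringsAsFactors = FALSE),
                     name = name,
                     nodes = unlist(genes, use.names = FALSE),
                     display = display)
  attr(g, "kgml_report") <- list(n_relations = length(relations),
                                 n_edges = nrow(g$edges),
                                 n_skipped = n_skipped,
                                 n_selfloop = n_selfloop,
                                 n_conflict = n_conflict,
                                 skipped_subtypes = table(skipped_subtypes))
  g
}
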