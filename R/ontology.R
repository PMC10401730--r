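# Compile the catalog's common concepts into an OWL 2 ontology: one class
# per concept, organised in sub-hierarchies by concept category, with
# existential ("some") restrictions attaching permissible-value classes
# (hasCategory) or numeric intervals (hasRange) to each concept class.

onto_base_iri <- "http://example.org/cohortquery/ontology"

scaffold_top <- "DataElement"
scaffold_fixed <- data.frame(
  name = c("DataElement", "DataProperty", "hasCategory", "hasRange",
           "PermissibleValue"),
  parent = c(NA, "DataElement", "DataProperty", "DataProperty",
             "DataElement"),
  kind = "scaffold", stringsAsFactors = FALSE)

#' Construct an ontology model
#'
#' The in-memory representation of the generated ontology: a class table
#' (name, parent, kind) forming a tree rooted at a single top class, and a
#' restriction table attaching permissible-value fillers (`hasCategory`)
#' or numeric intervals (`hasRange`) to concept classes.
#'
#' @param classes Data frame with columns `name`, `parent` (`NA` for the
#'   root), `kind` (`"scaffold"`, `"concept"`, `"category_value"`).
#' @param restrictions Data frame with columns `class`, `property`
#'   (`"hasCategory"`/`"hasRange"`), `filler` (category label, `""` for
#'   ranges), `min`, `max` (`NA` for categories).
#' @return An object of class `cq_ontology_model`.
#' @export
ontology_model <- function(classes = NULL, restrictions = NULL) {
  classes <- classes %||% empty_df(c("name", "parent", "kind"))
  restrictions <- restrictions %||%
    data.frame(class = character(), property = character(),
               filler = character(), min = numeric(), max = numeric(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(classes$name)) {
    cq_abort("cq_validation_error",
             sprintf("duplicate ontology class name: '%s'",
                     classes$name[duplicated(classes$name)][1]))
  }
  rownames(classes) <- NULL
  rownames(restrictions) <- NULL
  structure(list(classes = classes, restrictions = restrictions),
            class = "cq_ontology_model")
}

#' @export
print.cq_ontology_model <- function(x, ...) {
  cat(sprintf("<ontology_model> %d classes (%d concepts), %d restrictions\n",
              nrow(x$classes), sum(x$classes$kind == "concept"),
              nrow(x$restrictions)))
  invisible(x)
}

#' Number of named classes in an ontology model
#'
#' Counts classes of all kinds, including the scaffold (top class,
#' sub-hierarchy classes, `DataProperty` with `hasCategory`/`hasRange`,
#' `PermissibleValue`) and the permissible-value classes, not only the
#' concept classes.
#'
#' @param model An [ontology_model()].
#' @return Integer class count.
#' @export
class_count <- function(model) {
  stopifnot(inherits(model, "cq_ontology_model"))
  nrow(model$classes)
}

#' Build the ontology from a harmonization catalog
#'
#' Creates one sub-hierarchy class per distinct concept category, one
#' concept class per common concept (so the path from the top class to any
#' concept class has exactly two edges), one permissible-value class per
#' distinct category label, and the restrictions: a `hasCategory` "some"
#' restriction per permissible value of each categorical concept, and
#' exactly one `hasRange` restriction per numeric concept. Output ordering
#' is deterministic (alphabetical), so equal catalogs serialize to
#' identical bytes.
#'
#' @param cat A [catalog()].
#' @return An [ontology_model()].
#' @export
build_ontology <- function(cat) {
  cn <- cat$concepts
  if (any(!nzchar(cn$category))) {
    cq_abort("cq_validation_error",
             sprintf("concept '%s' has an empty category",
                     cn$concept_id[!nzchar(cn$category)][1]))
  }
  cn <- cn[order(cn$category, cn$label), , drop = FALSE]
  categories <- sort(unique(cn$category))

  classes <- scaffold_fixed
  if (length(categories)) {
    classes <- rbind(classes,
                     data.frame(name = categories, parent = scaffold_top,
                                kind = "scaffold", stringsAsFactors = FALSE))
  }

  restr <- list()
  value_labels <- character()
  if (nrow(cn)) {
    classes <- rbind(classes,
                     data.frame(name = cn$label, parent = cn$category,
                                kind = "concept", stringsAsFactors = FALSE))
    for (i in seq_len(nrow(cn))) {
      spec <- parse_code_spec(cn$code_spec[i])
      if (cn$data_type[i] == "categorical") {
        tab <- spec$categories
        value_labels <- c(value_labels, tab$label)
        restr[[length(restr) + 1L]] <- data.frame(
          class = cn$label[i], property = "hasCategory", filler = tab$label,
          min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
      } else {
        restr[[length(restr) + 1L]] <- data.frame(
          class = cn$label[i], property = "hasRange", filler = "",
          min = spec$range[1], max = spec$range[2], stringsAsFactors = FALSE)
      }
    }
  }
  value_labels <- sort(unique(value_labels))
  if (length(value_labels)) {
    classes <- rbind(classes,
                     data.frame(name = value_labels,
                                parent = "PermissibleValue",
                                kind = "category_value",
                                stringsAsFactors = FALSE))
  }
  restrictions <- if (length(restr)) do.call(rbind, restr) else NULL
  ontology_model(classes = classes, restrictions = restrictions)
}

class_iri <- function(name) paste0(onto_base_iri, "#", slugify(name))

#' Serialize an ontology model to OWL 2 RDF/XML
#'
#' Class IRIs are slugs of the display names; display names are kept as
#' `rdfs:label`. `hasCategory` restrictions are existential restrictions
#' onto the permissible-value classes; `hasRange` restrictions are
#' existential restrictions onto an `xsd:decimal` datatype restricted by
#' `xsd:minInclusive`/`xsd:maxInclusive`. Element order is deterministic.
#'
#' @param model An [ontology_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_owl <- function(model, path) {
  stopifnot(inherits(model, "cq_ontology_model"))
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "xmlns:rdfs" = "http://www.w3.org/2000/01/rdf-schema#",
    "xmlns:owl" = "http://www.w3.org/2002/07/owl#",
    "xmlns:xsd" = "http://www.w3.org/2001/XMLSchema#",
    "xml:base" = onto_base_iri)
  onto <- xml2::xml_add_child(doc, "owl:Ontology")
  xml2::xml_set_attr(onto, "rdf:about", onto_base_iri)

  cls <- model$classes
  for (i in seq_len(nrow(cls))) {
    node <- xml2::xml_add_child(doc, "owl:Class")
    xml2::xml_set_attr(node, "rdf:about", class_iri(cls$name[i]))
    lab <- xml2::xml_add_child(node, "rdfs:label")
    xml2::xml_set_text(lab, cls$name[i])
    kind <- xml2::xml_add_child(node, "rdfs:comment")
    xml2::xml_set_text(kind, paste0("kind=", cls$kind[i]))
    if (!is.na(cls$parent[i])) {
      sub <- xml2::xml_add_child(node, "rdfs:subClassOf")
      xml2::xml_set_attr(sub, "rdf:resource", class_iri(cls$parent[i]))
    }
    rs <- model$restrictions[model$restrictions$class == cls$name[i], ,
                             drop = FALSE]
    for (j in seq_len(nrow(rs))) {
      sub <- xml2::xml_add_child(node, "rdfs:subClassOf")
      rnode <- xml2::xml_add_child(sub, "owl:Restriction")
      prop <- xml2::xml_add_child(rnode, "owl:onProperty")
      xml2::xml_set_attr(prop, "rdf:resource", class_iri(rs$property[j]))
      if (rs$property[j] == "hasCategory") {
        some <- xml2::xml_add_child(rnode, "owl:someValuesFrom")
        xml2::xml_set_attr(some, "rdf:resource", class_iri(rs$filler[j]))
      } else {
        some <- xml2::xml_add_child(rnode, "owl:someValuesFrom")
        dt <- xml2::xml_add_child(some, "rdfs:Datatype")
        on <- xml2::xml_add_child(dt, "owl:onDatatype")
        xml2::xml_set_attr(on, "rdf:resource",
                           "http://www.w3.org/2001/XMLSchema#decimal")
        wr <- xml2::xml_add_child(dt, "owl:withRestrictions")
        xml2::xml_set_attr(wr, "rdf:parseType", "Collection")
        lo <- xml2::xml_add_child(wr, "rdf:Description")
        lon <- xml2::xml_add_child(lo, "xsd:minInclusive")
        xml2::xml_set_text(lon, fmt_num(rs$min[j]))
        hi <- xml2::xml_add_child(wr, "rdf:Description")
        hin <- xml2::xml_add_child(hi, "xsd:maxInclusive")
        xml2::xml_set_text(hin, fmt_num(rs$max[j]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse an OWL 2 RDF/XML file back into an ontology model
#'
#' Restores the class table (names from `rdfs:label`, kinds from the
#' serialized kind annotation, parents from plain `rdfs:subClassOf` links)
#' and the restriction multiset. Round trips through [serialize_owl()]
#' preserve class count, hierarchy edges and restrictions.
#'
#' @param path OWL RDF/XML file path.
#' @return An [ontology_model()].
#' @export
parse_owl <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    cq_abort("cq_parse_error",
             sprintf("malformed OWL document '%s': %s", path,
                     conditionMessage(e)))
  })
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#",
          xsd = "http://www.w3.org/2001/XMLSchema#")
  cls_nodes <- xml2::xml_find_all(doc, "/rdf:RDF/owl:Class", ns)
  iri_name <- character()
  rows <- list()
  restr <- list()
  for (node in cls_nodes) {
    iri <- xml2::xml_attr(node, "about")
    name <- xml2::xml_text(xml2::xml_find_first(node, "./rdfs:label", ns))
    kind <- sub("^kind=", "",
                xml2::xml_text(xml2::xml_find_first(node, "./rdfs:comment",
                                                    ns)))
    iri_name[iri] <- name
    parents <- xml2::xml_find_all(node, "./rdfs:subClassOf[@rdf:resource]",
                                  ns)
    parent_iri <- if (length(parents)) {
      xml2::xml_attr(parents[[1]], "resource")
    } else NA_character_
    rows[[length(rows) + 1L]] <- list(name = name, parent_iri = parent_iri,
                                      kind = kind)
    rnodes <- xml2::xml_find_all(node,
                                 "./rdfs:subClassOf/owl:Restriction", ns)
    for (rn in rnodes) {
      prop_iri <- xml2::xml_attr(xml2::xml_find_first(rn, "./owl:onProperty",
                                                      ns), "resource")
      prop <- if (grepl("hascategory$", prop_iri)) "hasCategory" else
        "hasRange"
      some <- xml2::xml_find_first(rn, "./owl:someValuesFrom", ns)
      if (prop == "hasCategory") {
        restr[[length(restr) + 1L]] <- list(
          class = name, property = prop,
          filler_iri = xml2::xml_attr(some, "resource"),
          min = NA_real_, max = NA_real_)
      } else {
        lo <- xml2::xml_text(xml2::xml_find_first(
          some, ".//xsd:minInclusive", ns))
        hi <- xml2::xml_text(xml2::xml_find_first(
          some, ".//xsd:maxInclusive", ns))
        restr[[length(restr) + 1L]] <- list(
          class = name, property = prop, filler_iri = "",
          min = as.numeric(lo), max = as.numeric(hi))
      }
    }
  }
  if (!length(rows)) return(ontology_model())
  classes <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    parent = unname(iri_name[vapply(rows, `[[`, "", "parent_iri")]),
    kind = vapply(rows, `[[`, "", "kind"), stringsAsFactors = FALSE)
  restrictions <- if (length(restr)) {
    data.frame(
      class = vapply(restr, `[[`, "", "class"),
      property = vapply(restr, `[[`, "", "property"),
      filler = vapply(restr, function(r) {
        if (nzchar(r$filler_iri)) unname(iri_name[r$filler_iri]) else ""
      }, character(1)),
      min = vapply(restr, `[[`, 0, "min"),
      max = vapply(restr, `[[`, 0, "max"), stringsAsFactors = FALSE)
  } else NULL
  ontology_model(classes = classes, restrictions = restrictions)
}

#' Export the class tree as JSON for a term browser
#'
#' @param model An [ontology_model()].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
ontology_tree_json <- function(model, path = NULL) {
  cls <- model$classes
  subs <- cls$name[cls$kind == "scaffold" & !is.na(cls$parent) &
                     cls$parent == scaffold_top &
                     !cls$name %in% c("DataProperty", "PermissibleValue")]
  tree <- lapply(sort(subs), function(s) {
    sort(cls$name[cls$kind == "concept" & cls$parent == s])
  })
  names(tree) <- sort(subs)
  json <- jsonlite::toJSON(tree, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
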