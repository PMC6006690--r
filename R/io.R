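# Readers and writers for the package's reaction-table TSV dialect, SBML
# Level 3 (with flux-bound annotations), and the plain-text model-condition
# file. The TSV dialect keeps fixtures human-writable:
#
#   id <TAB> equation <TAB> direction <TAB> in_taxon <TAB> is_polymer <TAB> gene_assoc
#
# with equation grammar "coef met + ... -> coef met + ..." ("<->" for
# reversible; omitted coefficients are 1). Exchange/demand reactions are
# generated from the model condition, never read from reaction tables.

TSV_HEADER <- c("id", "equation", "direction", "in_taxon", "is_polymer",
                "gene_assoc")

parse_equation <- function(eq, line, id) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("line ", line, " (", id, "): equation lacks '->' or '<->'")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("line ", line, " (", id, "): malformed equation '", eq, "'")
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?\\s+)?(\\S+)$", tm))[[1]]
      if (length(m) != 3L || !nzchar(m[3])) {
        stop("line ", line, " (", id, "): malformed term '", tm, "'")
      }
      coef <- if (nzchar(trimws(m[2]))) {
        cs <- trimws(m[2])
        if (grepl("/", cs, fixed = TRUE)) {
          parts <- as.numeric(strsplit(cs, "/", fixed = TRUE)[[1]])
          parts[1] / parts[2]
        } else as.numeric(cs)
      } else 1
      met <- m[3]
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (met in names(rhs)) {
    st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  }
  list(stoichiometry = st[st != 0], arrow = arrow)
}

parse_flag <- function(x, line, what) {
  x <- tolower(trimws(x))
  if (x %in% c("true", "t", "1", "yes")) return(TRUE)
  if (x %in% c("false", "f", "0", "no")) return(FALSE)
  stop("line ", line, ": cannot parse ", what, " flag '", x, "'")
}

#' Read a reaction table (TSV dialect)
#'
#' Parses the package's tab-separated reaction dialect into a list of
#' [reaction()] objects. Rows with an empty direction column are imported as
#' `REVERSIBLE` with a warning -- never inferred silently.
#'
#' @param path Path to a TSV file with header
#'   `id, equation, direction, in_taxon, is_polymer, gene_assoc`.
#' @return Named list of `reaction_spec`.
#' @export
read_reaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), TSV_HEADER)) {
    stop("line 1: expected header '", paste(TSV_HEADER, collapse = "\\t"), "'")
  }
  rxns <- list()
  n_unset <- 0L
  for (k in seq_along(lines)[-1]) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    length(fields) <- 6L
    fields[is.na(fields)] <- ""
    id <- trimws(fields[1])
    if (!nzchar(id)) stop("line ", k, ": empty reaction id")
    eq <- parse_equation(fields[2], k, id)
    dir <- toupper(trimws(fields[3]))
    if (!nzchar(dir)) {
      n_unset <- n_unset + 1L
      dir <- "REVERSIBLE"
    } else if (dir == "" || !dir %in% DIRECTIONS) {
      stop("line ", k, " (", id, "): unknown direction '", fields[3], "'")
    }
    r <- reaction(id, eq$stoichiometry, direction = dir,
                  in_taxonomic_range = parse_flag(fields[4], k, "in_taxon"),
                  is_polymerization = parse_flag(fields[5], k, "is_polymer"),
                  gene_associated = parse_flag(fields[6], k, "gene_assoc"))
    if (id %in% names(rxns)) stop("line ", k, ": duplicate reaction id '", id, "'")
    rxns[[id]] <- r
  }
  if (n_unset > 0L) {
    warning(n_unset, " reaction(s) had no explicit direction; ",
            "imported as REVERSIBLE")
  }
  rxns
}

format_equation <- function(r) {
  st <- r$stoichiometry
  fmt_side <- function(s) {
    if (!length(s)) return("")
    paste(ifelse(abs(s) == 1, names(s),
                 paste(format(abs(s), trim = TRUE), names(s))),
          collapse = " + ")
  }
  arrow <- if (r$direction == "REVERSIBLE") "<->" else "->"
  paste(fmt_side(st[st < 0]), arrow, fmt_side(st[st > 0]))
}

#' Write a reaction table (TSV dialect)
#'
#' @param reactions Named list of `reaction_spec` (or a `metabolic_model`,
#'   whose reactions are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(reactions, path) {
  if (inherits(reactions, "metabolic_model")) reactions <- reactions$reactions
  rows <- vapply(reactions, function(r) {
    paste(r$id, format_equation(r), r$direction,
          tolower(r$in_taxonomic_range), tolower(r$is_polymerization),
          tolower(r$gene_associated), sep = "\t")
  }, "")
  writeLines(c(paste(TSV_HEADER, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a model-condition file
#'
#' Plain-text format with `NUTRIENTS`, `SECRETIONS`, `BIOMASS` section
#' headers and one metabolite id (plus an optional number: uptake bound for
#' nutrients, coefficient for biomass) per line. `#` starts a comment.
#'
#' @param path Path to the condition file.
#' @param default_uptake Uptake bound for nutrients listed without one
#'   (default 10 flux units).
#' @return A [model_condition()].
#' @export
read_condition <- function(path, default_uptake = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- NULL
  nutrients <- numeric(0); secretions <- character(0); biomass <- numeric(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (toupper(ln) %in% c("NUTRIENTS", "SECRETIONS", "BIOMASS")) {
      section <- toupper(ln)
      next
    }
    if (is.null(section)) {
      stop("line ", k, ": entry '", ln, "' before any section header")
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    id <- parts[1]
    val <- if (length(parts) > 1L) as.numeric(parts[2]) else NA_real_
    if (length(parts) > 1L && is.na(val)) {
      stop("line ", k, ": cannot parse number in '", ln, "'")
    }
    switch(section,
           NUTRIENTS = nutrients[id] <- if (is.na(val)) default_uptake else val,
           SECRETIONS = secretions <- c(secretions, id),
           BIOMASS = biomass[id] <- if (is.na(val)) 1 else val)
  }
  model_condition(nutrients = nutrients, secretions = secretions,
                  biomass = biomass)
}

#' Write a model-condition file
#'
#' @param condition A [model_condition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition <- function(condition, path) {
  lines <- c("NUTRIENTS",
             paste(names(condition$nutrients),
                   format(unname(condition$nutrients), trim = TRUE)),
             "SECRETIONS",
             condition$secretions,
             "BIOMASS",
             paste(names(condition$biomass),
                   format(unname(condition$biomass), trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic model
#'
#' @param path Path to a reaction table (TSV dialect) or an SBML L3 file.
#' @param format `"tsv"` or `"sbml"`.
#' @param condition A [model_condition()], or the path of a condition file;
#'   `NULL` gives an empty condition (no nutrients, no biomass).
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("tsv", "sbml"), condition = NULL) {
  format <- match.arg(format)
  if (is.character(condition)) condition <- read_condition(condition)
  if (is.null(condition)) condition <- model_condition()
  rxns <- switch(format,
                 tsv = read_reaction_table(path),
                 sbml = read_sbml_reactions(path))
  metabolic_model(unname(rxns), condition)
}

#' Write a metabolic model
#'
#' Writes the reaction network (the condition is written separately with
#' [write_condition()]). [read_model()] inverts the result losslessly for
#' ids, stoichiometries, directions, and the taxon/polymerization/gene flags.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tsv = write_reaction_table(model$reactions, path),
         sbml = write_sbml(model, path))
  invisible(path)
}

# --- SBML L3 (core + fbc flux bounds) -------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
GFR_NS <- "https://gapfillr.invalid/annotations"

sbml_bound_ids <- function(direction) {
  switch(direction,
         L2R = c("bound_zero", "bound_upper"),
         R2L = c("bound_lower", "bound_zero"),
         REVERSIBLE = c("bound_lower", "bound_upper"))
}

write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_NS, level = "3", version = "1",
                            "xmlns:fbc" = FBC_NS, "xmlns:gapfillr" = GFR_NS,
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  met_sid <- stats::setNames(sprintf("M_%04d", seq_along(model$metabolites)),
                             model$metabolites)
  for (met in model$metabolites) {
    xml2::xml_add_child(species, "species", id = met_sid[[met]], name = met,
                        compartment = "c", constant = "false",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false")
  }
  params <- xml2::xml_add_child(mdl, "listOfParameters")
  for (p in list(c("bound_lower", "-3000"), c("bound_zero", "0"),
                 c("bound_upper", "3000"))) {
    xml2::xml_add_child(params, "parameter", id = p[1], value = p[2],
                        constant = "true")
  }
  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_along(model$reactions)) {
    r <- model$reactions[[k]]
    bounds <- sbml_bound_ids(r$direction)
    rn <- xml2::xml_add_child(rxns, "reaction", id = sprintf("R_%04d", k),
                              name = r$id, fast = "false",
                              reversible = tolower(r$direction == "REVERSIBLE"),
                              "fbc:lowerFluxBound" = bounds[1],
                              "fbc:upperFluxBound" = bounds[2])
    ann <- xml2::xml_add_child(rn, "annotation")
    xml2::xml_add_child(ann, "gapfillr:flags",
                        in_taxonomic_range = tolower(r$in_taxonomic_range),
                        is_polymerization = tolower(r$is_polymerization),
                        gene_associated = tolower(r$gene_associated))
    st <- r$stoichiometry
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (met in names(st)[st < 0]) {
        xml2::xml_add_child(lr, "speciesReference", species = met_sid[[met]],
                            stoichiometry = format(-st[[met]], trim = TRUE),
                            constant = "true")
      }
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (met in names(st)[st > 0]) {
        xml2::xml_add_child(lp, "speciesReference", species = met_sid[[met]],
                            stoichiometry = format(st[[met]], trim = TRUE),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_sbml_reactions <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  met_of <- stats::setNames(sname, sid)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rn <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- list()
  for (node in rn) {
    id <- xml2::xml_attr(node, "name")
    if (is.na(id)) id <- xml2::xml_attr(node, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, paste0("./s:", tag, "/s:speciesReference"), ns)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      unname(met_of[xml2::xml_attr(refs, "species")]))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    lb_id <- xml2::xml_attr(node, "lowerFluxBound")
    ub_id <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(parval)) parval[[lb_id]] else NA
    ub <- if (!is.na(ub_id) && ub_id %in% names(parval)) parval[[ub_id]] else NA
    direction <- if (!is.na(lb) && !is.na(ub)) {
      if (lb < 0 && ub > 0) "REVERSIBLE" else if (ub <= 0) "R2L" else "L2R"
    } else if (identical(xml2::xml_attr(node, "reversible"), "true")) {
      "REVERSIBLE"
    } else "L2R"
    flags <- xml2::xml_find_first(node, ".//*[local-name() = 'flags']")
    flag <- function(attr, default) {
      if (inherits(flags, "xml_missing")) return(default)
      v <- xml2::xml_attr(flags, attr)
      if (is.na(v)) default else identical(tolower(v), "true")
    }
    rxns[[id]] <- reaction(id, st, direction = direction,
                           in_taxonomic_range = flag("in_taxonomic_range", TRUE),
                           is_polymerization = flag("is_polymerization", FALSE),
                           gene_associated = flag("gene_associated", FALSE))
  }
  rxns
}
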