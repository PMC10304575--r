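# SBML Level 3 (core + FBC v2) reader and writer built on xml2.
# The writer emits flux bounds as FBC parameters, the objective as an FBC
# objective, species formula/charge as FBC attributes, genes as FBC gene
# products, and GPR strings / subsystems in COBRA-style notes so that
# boolean rules survive a round trip without being parsed. The reader
# accepts both that convention and FBC geneProductAssociation trees (as
# written by mainstream COBRA tools), which it flattens back to a string.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_check_sid <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad) > 0) {
    stop(sprintf("%s id(s) not SBML-compatible (need [A-Za-z_][A-Za-z0-9_]*): %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  }
}

num17 <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)

write_model_sbml <- function(model, path) {
  sbml_check_sid(model$metabolites$id, "metabolite")
  sbml_check_sid(model$reactions$id, "reaction")
  sbml_check_sid(names(model$compartments), "compartment")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" name="%s" constant="true"/>',
            names(model$compartments), esc(unname(model$compartments))),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula)) extra <- sprintf('%s fbc:chemicalFormula="%s"', extra, m$formula)
    if (!is.na(m$charge)) extra <- sprintf('%s fbc:charge="%d"', extra, as.integer(m$charge))
    out <- c(out, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      m$id, esc(m$name), m$compartment, extra))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    out <- c(out,
             sprintf('      <parameter id="bnd_%d_lb" value="%s" constant="true"/>',
                     i, num17(r$lower_bound)),
             sprintf('      <parameter id="bnd_%d_ub" value="%s" constant="true"/>',
                     i, num17(r$upper_bound)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    out <- c(out, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="bnd_%d_lb" fbc:upperFluxBound="bnd_%d_ub">',
      r$id, esc(r$name), if (r$lower_bound < 0) "true" else "false", i, i))
    if (nzchar(r$gpr) || nzchar(r$subsystem)) {
      out <- c(out, '        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      if (nzchar(r$gpr)) out <- c(out, sprintf('          <p>GENE_ASSOCIATION: %s</p>', esc(r$gpr)))
      if (nzchar(r$subsystem)) out <- c(out, sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)))
      out <- c(out, '        </body></notes>')
    }
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs) > 0) {
      out <- c(out, '        <listOfReactants>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(subs), num17(-unname(subs))),
               '        </listOfReactants>')
    }
    if (length(prods) > 0) {
      out <- c(out, '        <listOfProducts>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(prods), num17(unname(prods))),
               '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>',
           sprintf('    <fbc:listOfObjectives fbc:activeObjective="obj">'),
           sprintf('      <fbc:objective fbc:id="obj" fbc:type="%s">',
                   model$objective$direction),
           '        <fbc:listOfFluxObjectives>',
           sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                   model$objective$reaction),
           '        </fbc:listOfFluxObjectives>',
           '      </fbc:objective>',
           '    </fbc:listOfObjectives>')
  if (length(model$genes) > 0) {
    sbml_check_sid(model$genes, "gene")
    out <- c(out, '    <fbc:listOfGeneProducts>',
             sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     model$genes, model$genes),
             '    </fbc:listOfGeneProducts>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  # Fail fast on anything malformed rather than leaving a bad artifact.
  invisible(xml2::read_xml(path))
}

# Namespace-agnostic helpers: third-party SBML may bind fbc to any prefix.
xfind <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}
xattr <- function(node, name, default = NA_character_) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit) == 0) default else unname(at[hit[1]])
}

# Flatten an FBC geneProductAssociation subtree into a boolean string.
flatten_gpa <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") return(xattr(node, "geneProduct"))
  parts <- vapply(kids, flatten_gpa, character(1))
  parts <- parts[nzchar(parts)]
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1) parts else paste(parts, collapse = " ")
}

notes_field <- function(rnode, key) {
  ps <- xfind(rnode, "p")
  for (p in ps) {
    txt <- trimws(xml2::xml_text(p))
    if (startsWith(txt, paste0(key, ":"))) {
      return(trimws(sub(paste0("^", key, ":"), "", txt)))
    }
  }
  ""
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("cannot parse SBML file '%s': %s", path, conditionMessage(e)))
  })
  mnode <- xfind(doc, "model")
  if (length(mnode) == 0) stop(sprintf("SBML file '%s' has no <model> element", path))
  mnode <- mnode[[1]]

  comps_nodes <- xfind(mnode, "compartment")
  comps <- stats::setNames(
    ifelse(is.na(vapply(comps_nodes, xattr, character(1), "name")),
           vapply(comps_nodes, xattr, character(1), "id"),
           vapply(comps_nodes, xattr, character(1), "name")),
    vapply(comps_nodes, xattr, character(1), "id"))

  sp_nodes <- xfind(mnode, "species")
  if (length(sp_nodes) == 0) stop(sprintf("SBML file '%s' declares no species", path))
  mets <- data.frame(
    id = vapply(sp_nodes, xattr, character(1), "id"),
    name = vapply(sp_nodes, function(n) {
      v <- xattr(n, "name"); if (is.na(v)) xattr(n, "id") else v
    }, character(1)),
    compartment = vapply(sp_nodes, xattr, character(1), "compartment"),
    formula = vapply(sp_nodes, xattr, character(1), "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp_nodes, xattr, character(1), "charge"))),
    stringsAsFactors = FALSE)

  par_nodes <- xfind(mnode, "parameter")
  pars <- stats::setNames(
    suppressWarnings(as.numeric(vapply(par_nodes, xattr, character(1), "value"))),
    vapply(par_nodes, xattr, character(1), "id"))

  rx_nodes <- xml2::xml_find_all(
    mnode, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop(sprintf("SBML file '%s' declares no reactions", path))
  n_rx <- length(rx_nodes)
  rxns <- empty_reaction_frame()
  stoich <- vector("list", n_rx)
  for (i in seq_len(n_rx)) {
    rn <- rx_nodes[[i]]
    rid <- xattr(rn, "id")
    lb_ref <- xattr(rn, "lowerFluxBound")
    ub_ref <- xattr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pars)) pars[[lb_ref]] else -DEFAULT_BOUND
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pars)) pars[[ub_ref]] else DEFAULT_BOUND

    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        sp <- xattr(ref, "species")
        coef <- suppressWarnings(as.numeric(xattr(ref, "stoichiometry", "1")))
        if (is.na(sp) || is.na(coef)) {
          stop(sprintf("SBML reaction '%s': malformed speciesReference", rid))
        }
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + sgn * coef
      }
    }
    st <- st[st != 0]

    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids) > 0) flatten_gpa(kids[[1]]) else ""
    } else notes_field(rn, "GENE_ASSOCIATION")
    nm <- xattr(rn, "name"); if (is.na(nm)) nm <- rid
    rxns <- rbind(rxns, data.frame(
      id = rid, name = nm, lower_bound = lb, upper_bound = ub,
      gpr = gpr, subsystem = notes_field(rn, "SUBSYSTEM"),
      stringsAsFactors = FALSE))
    stoich[[i]] <- st
  }
  names(stoich) <- rxns$id

  fobj <- xml2::xml_find_first(mnode, ".//*[local-name()='fluxObjective']")
  if (inherits(fobj, "xml_missing")) {
    stop(sprintf("SBML file '%s' declares no flux objective", path))
  }
  obj_rxn <- xattr(fobj, "reaction")
  obj_node <- xml2::xml_find_first(mnode, ".//*[local-name()='objective']")
  direction <- xattr(obj_node, "type", "maximize")

  gp_nodes <- xfind(mnode, "geneProduct")
  genes <- vapply(gp_nodes, function(n) {
    v <- xattr(n, "label"); if (is.na(v)) xattr(n, "id") else v
  }, character(1))

  if (length(comps) == 0) {
    comps <- stats::setNames(unique(mets$compartment), unique(mets$compartment))
  }
  mid <- xattr(mnode, "id"); if (is.na(mid)) mid <- "model"
  metabolic_model(id = mid, metabolites = mets, reactions = rxns,
                  stoichiometry = stoich, compartments = comps,
                  objective = list(reaction = obj_rxn, direction = direction),
                  genes = genes)
}
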