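# Timetree assembly: backbone merging and pendant-length grafting.
#
# A graft instruction places one missing species into an ultrametric
# backbone. In sister mode the instruction carries the species' sister taxon
# and its pendant length (PL, myr) as read from a published timetree; the
# species is attached on the sister's terminal branch at age PL. When the
# requested PL is not younger than the sister's own backbone PL p, attaching
# at PL would create (or pass) the sister's parent node, so both species are
# instead attached at age p - epsilon (default 0.1 myr), keeping the tree
# binary and ultrametric. In genus_base mode (used when no consensus sister
# exists) the species is attached on the stem branch of its genus.

# Insert a new tip by subdividing the branch above `where` at `position`
# units above it; the new tip hangs from the created node with
# `tip_length`. Direct edge-matrix surgery: branch lengths are carried as
# exact doubles (serialisation round-trips would truncate them).
insert_tip <- function(tree, label, where, position, tip_length) {
  ntip <- ape::Ntip(tree)
  e <- which(tree$edge[, 2L] == where)
  if (length(e) != 1L) stop("cannot attach above the root")
  L <- tree$edge.length[e]
  if (position <= 0 || position >= L)
    stop("attachment position ", format(position),
         " outside the target branch (length ", format(L), ")")
  edge <- tree$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L  # make room for the new tip id
  new_tip <- ntip + 1L
  new_node <- ntip + tree$Nnode + 2L
  parent <- edge[e, 1L]
  child <- edge[e, 2L]
  edge[e, ] <- c(parent, new_node)
  edge <- rbind(edge, c(new_node, child), c(new_node, new_tip))
  len <- c(tree$edge.length, position, tip_length)
  len[e] <- L - position
  out <- list(edge = edge, edge.length = len,
              tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Assembly configuration
#'
#' @param epsilon polytomy-avoidance offset in myr applied when a requested
#'   pendant length conflicts with the anchor's backbone pendant length.
#' @param genus_delimiter regular expression splitting a tip label into
#'   genus and epithet; the genus is the first field.
#' @return a list with class \code{assembly_config}.
#' @export
assembly_config <- function(epsilon = 0.1, genus_delimiter = "_") {
  stopifnot(is.numeric(epsilon), epsilon > 0)
  structure(list(epsilon = epsilon, genus_delimiter = genus_delimiter),
            class = "assembly_config")
}

genus_of <- function(labels, config) {
  vapply(strsplit(labels, config$genus_delimiter, fixed = TRUE),
         `[[`, character(1), 1L)
}

#' Graft one species onto a timetree
#'
#' @param tree ultrametric \code{phylo} backbone.
#' @param species tip label of the species to add (must be absent).
#' @param anchor sister tip label (\code{mode = "sister"}) or genus name
#'   (\code{mode = "genus_base"}).
#' @param pl requested pendant length in myr (sister mode).
#' @param mode \code{"sister"} or \code{"genus_base"}.
#' @param config an \code{\link{assembly_config}}.
#' @return list with elements \code{tree} (the expanded timetree) and
#'   \code{record} (species, attachment age, rule applied, and the requested,
#'   backbone and final PLs for conflict bookkeeping).
#' @export
graft_tip <- function(tree, species, anchor, pl = NA_real_,
                      mode = c("sister", "genus_base"),
                      config = assembly_config()) {
  mode <- match.arg(mode)
  if (species %in% tree$tip.label) stop("species already in tree: ", species)
  eps <- config$epsilon

  if (mode == "sister") {
    if (!anchor %in% tree$tip.label) stop("anchor not in tree: ", anchor)
    if (!is.finite(pl) || pl <= 0) stop("sister-mode instruction needs pl > 0")
    p <- unname(pendant_lengths(tree)[anchor])
    if (pl < p) {
      attach_age <- pl
      rule <- "as_given"
      final_pl <- pl
    } else {
      if (p - eps <= 0)
        stop("anchor PL (", format(p), ") too short to apply the ",
             format(eps), " myr conflict offset")
      attach_age <- p - eps
      rule <- "conflict_offset"
      final_pl <- p - eps
    }
    out <- insert_tip(tree, species, where = match(anchor, tree$tip.label),
                      position = attach_age, tip_length = attach_age)
    record <- list(species = species, anchor = anchor, mode = mode,
                   attachment_age = attach_age, rule = rule,
                   requested_pl = pl, backbone_pl = p, final_pl = final_pl)
  } else {
    members <- tree$tip.label[genus_of(tree$tip.label, config) == anchor]
    if (length(members) == 0L) stop("genus not in tree: ", anchor)
    ages <- node_ages(tree)
    if (length(members) == 1L) {
      node <- match(members, tree$tip.label)
      crown <- 0
    } else {
      node <- tree_mrca(tree, members)
      crown <- ages[node]
    }
    if (node == ape::Ntip(tree) + 1L)
      stop("genus clade is the whole tree; no stem branch to attach to")
    stem <- ages[tree$edge[tree$edge[, 2L] == node, 1L]]
    attach_age <- (crown + stem) / 2
    out <- insert_tip(tree, species, where = node,
                      position = attach_age - crown, tip_length = attach_age)
    record <- list(species = species, anchor = anchor, mode = mode,
                   attachment_age = attach_age, rule = "genus_base",
                   requested_pl = NA_real_, backbone_pl = NA_real_,
                   final_pl = attach_age)
  }
  list(tree = out, record = record)
}

#' Apply an ordered list of graft instructions
#'
#' Instructions are applied in input order; a later instruction may anchor
#' on a species grafted earlier. Failures (missing anchor, duplicate
#' species, anchor PL too short for the conflict offset) skip the
#' instruction and are reported; the run never aborts mid-list.
#'
#' @param tree ultrametric \code{phylo} backbone.
#' @param instructions data frame with columns \code{species}, \code{mode},
#'   \code{anchor}, \code{pl_myr} and optionally \code{source} (see
#'   \code{\link{read_graft_table}}).
#' @param config an \code{\link{assembly_config}}.
#' @return list with \code{tree} and an \code{assembly_report}: data frames
#'   \code{grafted} (species, attachment age, rule), \code{conflicts}
#'   (species, requested/backbone/final PL) and \code{skipped} (species,
#'   reason).
#' @export
apply_grafts <- function(tree, instructions, config = assembly_config()) {
  grafted <- list(); conflicts <- list(); skipped <- list()
  if (is.null(instructions) || nrow(instructions) == 0L)
    return(list(tree = tree, report = assembly_report(grafted, conflicts, skipped)))
  for (i in seq_len(nrow(instructions))) {
    ins <- instructions[i, ]
    res <- tryCatch(
      graft_tip(tree, species = ins$species, anchor = ins$anchor,
                pl = if ("pl_myr" %in% names(ins)) ins$pl_myr else NA_real_,
                mode = ins$mode, config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species = ins$species, reason = conditionMessage(res))
      next
    }
    tree <- res$tree
    rec <- res$record
    grafted[[length(grafted) + 1L]] <-
      data.frame(species = rec$species, anchor = rec$anchor, mode = rec$mode,
                 attachment_age = rec$attachment_age, rule = rec$rule)
    if (identical(rec$rule, "conflict_offset")) {
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(species = rec$species, requested_pl = rec$requested_pl,
                   backbone_pl = rec$backbone_pl, final_pl = rec$final_pl)
    }
  }
  list(tree = tree, report = assembly_report(grafted, conflicts, skipped))
}

assembly_report <- function(grafted, conflicts, skipped, merged_nodes = NULL) {
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(list(
    grafted = bind(grafted, data.frame(species = character(), anchor = character(),
                                       mode = character(), attachment_age = numeric(),
                                       rule = character())),
    conflicts = bind(conflicts, data.frame(species = character(), requested_pl = numeric(),
                                           backbone_pl = numeric(), final_pl = numeric())),
    skipped = bind(skipped, data.frame(species = character(), reason = character())),
    merged_nodes = merged_nodes
  ), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembly report: ", nrow(x$grafted), " grafted (",
      nrow(x$conflicts), " via conflict offset), ",
      nrow(x$skipped), " skipped\n", sep = "")
  if (!is.null(x$merged_nodes))
    cat("backbone merge: ", nrow(x$merged_nodes), " shared nodes age-averaged\n", sep = "")
  invisible(x)
}

# Internal: for each internal node of `tree`, the sorted restriction of its
# clade tip set to `shared`; NA for restrictions of size < 2.
restricted_keys <- function(tree, shared) {
  ntip <- ape::Ntip(tree)
  sets <- clade_tip_sets(tree)
  vapply(seq_len(tree$Nnode) + ntip, function(nd) {
    s <- intersect(sets[[nd]], shared)
    if (length(s) < 2L) NA_character_ else paste(sort(s), collapse = "\r")
  }, character(1))
}

#' Merge two backbone timetrees
#'
#' Combines a primary and a secondary timetree over their shared taxa. The
#' topology of the primary is kept. Every internal node of the primary that
#' is the MRCA of its shared-taxon restriction, and whose restricted clade
#' also occurs in the secondary, receives the arithmetic mean of the two
#' source ages; ages are then adjusted bottom-up so every parent stays
#' strictly older than its children (a parent younger than a child is raised
#' to the child age plus \code{config$epsilon}). Taxa present only in the
#' secondary are converted to sister/PL graft instructions (sister = the
#' shared tip with the youngest common ancestor in the secondary, PL = that
#' ancestor's age) and grafted in order of decreasing PL.
#'
#' @param primary,secondary ultrametric \code{phylo} trees sharing at least
#'   two tips.
#' @param config an \code{\link{assembly_config}}.
#' @return list with \code{tree}, an \code{assembly_report} (with a
#'   \code{merged_nodes} table of averaged ages), and the generated
#'   \code{instructions}.
#' @export
merge_backbones <- function(primary, secondary, config = assembly_config()) {
  shared <- intersect(primary$tip.label, secondary$tip.label)
  if (length(shared) < 2L) stop("backbones share fewer than 2 taxa")

  ages_p <- node_ages(primary)
  ages_s <- node_ages(secondary)
  ntip_p <- ape::Ntip(primary)
  keys_p <- restricted_keys(primary, shared)
  keys_s <- restricted_keys(secondary, shared)
  sets_p <- clade_tip_sets(primary)
  sets_s <- clade_tip_sets(secondary)

  # node is the primary-side representative of its restricted clade iff it is
  # the MRCA of the restriction (i.e. the shallowest node with that key)
  merged <- list()
  new_ages <- ages_p
  for (j in seq_len(primary$Nnode)) {
    nd <- ntip_p + j
    key <- keys_p[j]
    if (is.na(key)) next
    S <- intersect(sets_p[[nd]], shared)
    if (ape::getMRCA(primary, match(S, primary$tip.label)) != nd) next
    m <- ape::getMRCA(secondary, match(S, secondary$tip.label))
    if (!setequal(intersect(sets_s[[m]], shared), S)) next
    avg <- (ages_p[nd] + ages_s[m]) / 2
    merged[[length(merged) + 1L]] <-
      data.frame(node = nd, age_primary = ages_p[nd], age_secondary = ages_s[m],
                 age_merged = avg)
    new_ages[nd] <- avg
  }
  merged_nodes <- if (length(merged)) do.call(rbind, merged) else
    data.frame(node = integer(), age_primary = numeric(),
               age_secondary = numeric(), age_merged = numeric())

  # bottom-up repair: averaging can invert local age order
  eo <- ape::reorder.phylo(primary, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1L]; ch <- eo$edge[i, 2L]
    if (new_ages[par] <= new_ages[ch])
      new_ages[par] <- new_ages[ch] + config$epsilon
  }
  out <- ages_to_edges(primary, new_ages)

  # secondary-only taxa become sister/PL instructions
  extra <- setdiff(secondary$tip.label, primary$tip.label)
  instructions <- NULL
  if (length(extra)) {
    rows <- lapply(extra, function(x) {
      div <- vapply(shared, function(s)
        ages_s[ape::getMRCA(secondary, match(c(x, s), secondary$tip.label))],
        numeric(1))
      sister <- names(div)[order(div, names(div))][1L]
      data.frame(species = x, mode = "sister", anchor = sister,
                 pl_myr = min(div), source = "secondary_backbone")
    })
    instructions <- do.call(rbind, rows)
    instructions <- instructions[order(-instructions$pl_myr, instructions$species), ]
    res <- apply_grafts(out, instructions, config)
    out <- res$tree
    report <- res$report
    report$merged_nodes <- merged_nodes
  } else {
    report <- assembly_report(list(), list(), list(), merged_nodes)
  }
  list(tree = out, report = report, instructions = instructions)
}

#' Read / write graft-instruction tables
#'
#' Tab-delimited text with header \code{species, mode, anchor, pl_myr,
#' source}; \code{pl_myr} may be empty for \code{genus_base} rows.
#'
#' @param file path to a delimited text file.
#' @return data frame of instructions.
#' @export
read_graft_table <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", "mode", "anchor", "pl_myr")
  if (!all(need %in% names(x)))
    stop("instruction table must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(x)) x$source <- ""
  x$pl_myr <- as.numeric(x$pl_myr)
  x
}

#' @rdname read_graft_table
#' @param instructions data frame of instructions.
#' @export
write_graft_table <- function(instructions, file) {
  write.table(instructions, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
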