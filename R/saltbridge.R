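# Salt-bridge detection: acid carboxylate oxygen to basic nitrogen
# contacts, multi-bridge networks and bidentate motifs, and the
# extended-sampling flag for mutations touching them.

.ACID_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASE_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.HIS_ATOMS <- c("ND1", "NE2")

#' Salt-bridge detection configuration
#'
#' @param cutoff maximum heavy-atom N-O distance, Angstrom (4.0 is the
#'   common literature convention).
#' @param include_his also treat histidine ND1/NE2 as basic nitrogens
#'   (off by default: protonation is rarely assignable without
#'   crystallographic evidence).
#' @param include_termini also use backbone termini (N-terminal N, OXT);
#'   off by default.
#' @return a `saltbridge_config` list.
#' @export
saltbridge_config <- function(cutoff = 4.0, include_his = FALSE,
                              include_termini = FALSE) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, include_his = include_his,
                 include_termini = include_termini),
            class = "saltbridge_config")
}

#' Detect salt bridges and salt-bridge networks
#'
#' Every acid-base residue pair with at least one carboxylate-oxygen to
#' basic-nitrogen distance within the cutoff forms an edge.  An edge is
#' bidentate when at least two distinct N-O pairs are within cutoff and
#' involve two distinct atoms on at least one side (e.g. both carboxylate
#' oxygens engaged).  Protonated carboxylates (ASH/GLH) are neutral and
#' are not treated as acids.
#'
#' @param s an `fep_structure`.
#' @param cfg a [saltbridge_config()].
#' @return a `bridge_graph`: list with data.frames `nodes` (`key`,
#'   `resid`, `role`) and `edges` (`acid`, `base`, `dist`, `n_pairs`,
#'   `bidentate`).
#' @export
detect_bridges <- function(s, cfg = saltbridge_config()) {
  stopifnot(inherits(s, "fep_structure"))
  a <- s$atoms[!s$atoms$hetero, , drop = FALSE]
  keys <- residue_key(a$chain, a$resno, a$insert)
  base_atoms <- .BASE_ATOMS
  if (cfg$include_his) base_atoms$HIS <- .HIS_ATOMS
  pick <- function(tab) {
    sel <- rep(FALSE, nrow(a))
    for (resid in names(tab))
      sel <- sel | (a$resid == resid & a$elety %in% tab[[resid]])
    sel
  }
  acid_sel <- pick(.ACID_ATOMS)
  base_sel <- pick(base_atoms)
  if (cfg$include_termini) {
    first_res <- !duplicated(a$chain)
    last_res <- !duplicated(a$chain, fromLast = TRUE)
    nterm_keys <- unique(keys[first_res])
    cterm_keys <- unique(keys[last_res])
    base_sel <- base_sel | (keys %in% nterm_keys & a$elety == "N")
    acid_sel <- acid_sel | (keys %in% cterm_keys & a$elety %in% c("O", "OXT"))
  }
  acid <- a[acid_sel, , drop = FALSE]; acid_key <- keys[acid_sel]
  base <- a[base_sel, , drop = FALSE]; base_key <- keys[base_sel]
  edges <- data.frame(acid = character(), base = character(),
                      dist = numeric(), n_pairs = integer(),
                      bidentate = logical(), stringsAsFactors = FALSE)
  if (nrow(acid) > 0 && nrow(base) > 0) {
    axyz <- as.matrix(acid[, c("x", "y", "z")])
    bxyz <- as.matrix(base[, c("x", "y", "z")])
    d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), `+`) -
      2 * axyz %*% t(bxyz)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    hit <- which(d <= cfg$cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pair_id <- paste(acid_key[hit[, 1]], base_key[hit[, 2]], sep = "~")
      for (pid in unique(pair_id)) {
        rows <- hit[pair_id == pid, , drop = FALSE]
        ak <- acid_key[rows[1, 1]]; bk <- base_key[rows[1, 2]]
        if (ak == bk) next # a terminus can't bridge itself
        o_atoms <- acid$elety[rows[, 1]]
        n_atoms <- base$elety[rows[, 2]]
        bident <- nrow(rows) >= 2 &&
          (length(unique(o_atoms)) >= 2 || length(unique(n_atoms)) >= 2)
        edges <- rbind(edges, data.frame(
          acid = ak, base = bk,
          dist = min(d[rows]), n_pairs = nrow(rows),
          bidentate = bident, stringsAsFactors = FALSE))
      }
    }
  }
  edges <- edges[order(edges$acid, edges$base), , drop = FALSE]
  rownames(edges) <- NULL
  node_keys <- unique(c(edges$acid, edges$base))
  res <- structure_residues(s)
  nodes <- data.frame(key = node_keys,
                      resid = res$resid[match(node_keys, res$key)],
                      role = ifelse(node_keys %in% edges$acid, "acid",
                                    "base"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cutoff = cfg$cutoff),
            class = "bridge_graph")
}

#' @export
print.bridge_graph <- function(x, ...) {
  cat("<bridge_graph> ", nrow(x$nodes), " charged residues, ",
      nrow(x$edges), " bridge(s) at cutoff ", x$cutoff, " A\n", sep = "")
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' Flag a mutation for extended FEP sampling
#'
#' Mutations made to residues participating in multiple salt bridges, or
#' in any bidentate bridge, face large electrostatic barriers to sampling
#' out of the initial conformation and should be run with extended
#' simulation time (100 ns per window).
#'
#' @param g a `bridge_graph` from [detect_bridges()].
#' @param m a `mutation_spec` (or a residue key string).
#' @return list with `flag` (logical) and `reason` (character naming the
#'   triggering partner residues, empty when not flagged).
#' @export
flag_extended_sampling <- function(g, m) {
  key <- if (inherits(m, "mutation_spec")) m$key else as.character(m)
  e <- g$edges[g$edges$acid == key | g$edges$base == key, , drop = FALSE]
  n_edges <- nrow(e)
  any_bident <- any(e$bidentate)
  flag <- n_edges >= 2 || any_bident
  partners <- setdiff(unique(c(e$acid, e$base)), key)
  reason <- if (!flag) "" else
    sprintf("participates in %d salt bridge(s)%s with %s", n_edges,
            if (any_bident) " (bidentate)" else "",
            paste(partners, collapse = ", "))
  list(flag = flag, reason = reason)
}

#' Export a bridge graph
#'
#' `write_bridge_tsv()` writes the edge list as TSV; `bridge_dot()`
#' renders the network in Graphviz DOT format for visualisation.
#'
#' @param g a `bridge_graph`.
#' @param path output file.
#' @return `path` invisibly (writer) or a character scalar (DOT).
#' @export
write_bridge_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bridge_tsv
#' @export
bridge_dot <- function(g) {
  lines <- c("graph saltbridges {",
             sprintf('  "%s" [shape=%s];', g$nodes$key,
                     ifelse(g$nodes$role == "acid", "box", "ellipse")),
             sprintf('  "%s" -- "%s" [label="%.2f"%s];', g$edges$acid,
                     g$edges$base, g$edges$dist,
                     ifelse(g$edges$bidentate, ",style=bold", "")),
             "}")
  paste(lines, collapse = "\n")
}
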