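#' @title Mapping cassette states onto the strain phylogeny
#' @name phylo_map
#' @description
#' Cassette states (LONG/SHORT) at the tips of the strain tree are
#' summarized by the Fitch small-parsimony minimum number of state changes
#' (exact on multifurcating trees via the standard intersection/union
#' generalization), compared against a permutation null of shuffled tip
#' labels, tabulated per phylogroup, and exported as iTOL COLORSTRIP
#' annotations. Tips with states outside the two-letter alphabet (PARTIAL,
#' NONE) are pruned before parsimony, because the interspersion claim
#' concerns the two cassette types only.
NULL

#' Read a strain tree from Newick
#'
#' @param x Newick text (containing `;`) or a file path.
#' @return An `ape` `phylo` object; duplicate tip labels are an error,
#'   multifurcations are preserved.
#' @export
read_tree <- function(x) {
  tr <- if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(x)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

# children of each node from the edge matrix
.children_of <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

#' Minimum number of state transitions on a tree (Fitch parsimony)
#'
#' Tips with states outside `alphabet` are pruned first. Internal nodes are
#' scored bottom-up; at a (possibly multifurcating) node the states kept are
#' those occurring in the largest number of child state sets, and the cost
#' increases by (number of children) minus that count — the standard
#' intersection/union rule, which attains the exact minimum on
#' multifurcations too.
#'
#' @param tree A `phylo` tree.
#' @param states Named character vector: tip -> state.
#' @param alphabet States to count over (default LONG/SHORT).
#' @return Integer: the minimal number of state changes.
#' @export
fitch_transitions <- function(tree, states,
                              alphabet = c("LONG", "SHORT")) {
  m <- .fitch_machine(tree, names(states)[states %in% alphabet])
  .fitch_count(m, match(states[m$tips], alphabet))
}

# Precompute the pruned tree traversal so repeated counts (permutation null)
# are cheap: postorder node list and children lists, tips first.
.fitch_machine <- function(tree, informative_tips) {
  keep <- tree$tip.label[tree$tip.label %in% informative_tips]
  if (length(keep) < 2)
    stop("fewer than 2 tips with states in the alphabet; ",
         "parsimony is undefined")
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  ord <- ape::reorder.phylo(tree, "postorder")
  list(tips = tree$tip.label, ntip = length(tree$tip.label),
       nnode = tree$Nnode, nodes = unique(ord$edge[, 1]),
       kids = .children_of(tree))
}

# Hartigan bottom-up pass over a two-state alphabet encoded as bitmasks
# (state 1 -> 1, state 2 -> 2, {both} -> 3); exact minimum on
# multifurcations: keep the states present in the most child sets, pay one
# change per child set lacking them.
.fitch_count <- function(m, tip_states) {
  sets <- integer(m$ntip + m$nnode)
  sets[seq_len(m$ntip)] <- tip_states
  cost <- 0L
  for (nd in m$nodes) {
    ch <- m$kids[[as.character(nd)]]
    cs <- sets[ch]
    n1 <- sum(bitwAnd(cs, 1L) > 0L)
    n2 <- sum(bitwAnd(cs, 2L) > 0L)
    k <- max(n1, n2)
    sets[nd] <- (if (n1 == k) 1L else 0L) + (if (n2 == k) 2L else 0L)
    cost <- cost + (length(ch) - k)
  }
  as.integer(cost)
}

#' Permutation test of phylogenetic interspersion
#'
#' Compares the observed Fitch transition count with counts under random
#' permutations of the informative tip states. A small percentile (few
#' permutations reach a count as low as observed) indicates phylogenetic
#' clustering of the states; a large one indicates interspersion
#' indistinguishable from random placement.
#'
#' @param tree A `phylo` tree.
#' @param states Named tip -> state vector.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alphabet Two-state alphabet.
#' @return List: `observed`, `perm_counts`, `percentile` (the add-one
#'   estimate of P(null count <= observed)).
#' @export
interspersion_test <- function(tree, states, n_perm = 1000, seed = 17,
                               alphabet = c("LONG", "SHORT")) {
  keep <- names(states)[states %in% alphabet &
                          names(states) %in% tree$tip.label]
  m <- .fitch_machine(tree, keep)
  st <- match(states[m$tips], alphabet)
  obs <- .fitch_count(m, st)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) .fitch_count(m, sample(st)),
           integer(1))
  })
  list(observed = obs, perm_counts = perm,
       percentile = (1 + sum(perm <= obs)) / (n_perm + 1))
}

#' Per-phylogroup cassette state summary
#'
#' @param states Named strain -> state vector.
#' @param phylogroups Named strain -> phylogroup vector.
#' @return data.frame: `phylogroup`, `n_long`, `n_short`, `n_partial`,
#'   `n_none`, `both_present` (TRUE iff the group holds both LONG and SHORT
#'   strains).
#' @export
phylogroup_summary <- function(states, phylogroups) {
  if (length(states) == 0)
    return(data.frame(phylogroup = character(), n_long = integer(),
                      n_short = integer(), n_partial = integer(),
                      n_none = integer(), both_present = logical(),
                      stringsAsFactors = FALSE))
  common <- intersect(names(states), names(phylogroups))
  st <- states[common]; pg <- phylogroups[common]
  rows <- lapply(sort(unique(pg)), function(g) {
    s <- st[pg == g]
    data.frame(phylogroup = g,
               n_long = sum(s == "LONG"), n_short = sum(s == "SHORT"),
               n_partial = sum(s == "PARTIAL"), n_none = sum(s == "NONE"),
               both_present = any(s == "LONG") && any(s == "SHORT"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.itol_default_palette <- c(LONG = "#1f78b4", SHORT = "#e31a1c",
                           PARTIAL = "#ff7f00", NONE = "#bdbdbd")

#' Export cassette states as an iTOL COLORSTRIP dataset
#'
#' @param states Named strain -> state vector.
#' @param palette Named state -> hex color vector.
#' @param label Dataset label shown in iTOL.
#' @return Character vector of dataset lines (header block, LEGEND, DATA).
#' @export
export_itol <- function(states, palette = .itol_default_palette,
                        label = "yih cassette variant") {
  used <- intersect(names(palette), unique(states))
  header <- c("DATASET_COLORSTRIP",
              "SEPARATOR TAB",
              paste0("DATASET_LABEL\t", label),
              "COLOR\t#1f78b4",
              "LEGEND_TITLE\tCassette variant",
              paste0("LEGEND_SHAPES\t",
                     paste(rep(1, length(used)), collapse = "\t")),
              paste0("LEGEND_COLORS\t",
                     paste(palette[used], collapse = "\t")),
              paste0("LEGEND_LABELS\t", paste(used, collapse = "\t")),
              "DATA")
  if (length(states) == 0) return(header)
  data_lines <- paste(names(states),
                      palette[as.character(states)],
                      as.character(states), sep = "\t")
  c(header, data_lines)
}

#' Parse an iTOL COLORSTRIP dataset back to a tip -> state map
#'
#' Inverse of [export_itol()] for round-trip checks: reads the lines after
#' `DATA`, using the third field (the label) as the state.
#'
#' @param lines Character vector as produced by [export_itol()].
#' @return Named character vector: tip -> state.
#' @export
parse_itol <- function(lines) {
  i <- match("DATA", lines)
  if (is.na(i)) stop("no DATA section found")
  if (i == length(lines)) return(setNames(character(0), character(0)))
  body <- lines[(i + 1):length(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  setNames(vapply(parts, `[`, character(1), 3),
           vapply(parts, `[`, character(1), 1))
}
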