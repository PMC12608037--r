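#' @title Synthetic strain-panel generator
#' @name synthetic_panel
#' @description
#' Generates a panel of annotated genomes that emulates the observed
#' architecture: a conserved UOG backbone identical across strains, a
#' cassette locus sitting strictly between two designated flanking UOGs
#' (labeled UOG217 and UOG236 by default), a long/short cassette state
#' evolving along a pure-birth tree by a per-branch Markov switch/loss
#' process, reversed gene order and strand for the short variant, i.i.d.
#' per-site protein divergence, and a pathotype label whose conditional
#' probabilities solve a configurable odds ratio against cassette type.
#' All ground truth is recorded so every pipeline stage can be verified.
NULL

#' Configuration for [simulate_panel()]
#'
#' @param n_strains Number of strains (>= 2).
#' @param seed RNG seed driving every random choice.
#' @param n_uogs Number of backbone UOGs (default 238, the size of the
#'   standard marker set).
#' @param contig_length Chromosome length in bp; `NULL` computes it from the
#'   gene layout plus a 5 kb margin.
#' @param intergenic_gap Gap between adjacent genes in bp (default 200, a
#'   typical bacterial intergenic distance).
#' @param root_state Cassette state at the tree root (`"LONG"` default).
#' @param switch_prob Per-branch probability of a LONG<->SHORT switch
#'   (default 0.05; a placeholder for the unknown real rate).
#' @param loss_prob Per-branch probability of complete cassette loss
#'   (absorbing NONE; default 0).
#' @param invert_short Write the short cassette in reversed gene order on
#'   the minus strand (default TRUE, emulating the observed reversal).
#' @param divergence Per-site protein substitution probability relative to
#'   the references (default 0.05; substitutions are uniform over the other
#'   19 residues, no indels).
#' @param target_or Target odds ratio of pathotype against cassette type
#'   (default 2.67).
#' @param baseline_pathogenic Baseline pathogenic fraction (default 0.5);
#'   the two conditional probabilities split the target OR symmetrically
#'   around this baseline on the odds scale.
#' @param n_phylogroups Number of phylogroups = deepest clades (default 8).
#' @param founder_clade_short Force exactly one LONG->SHORT switch on the
#'   branch to the root's first child, producing a perfect two-clade
#'   structure (default FALSE).
#' @param uog_protein_len Backbone marker protein length (default 90).
#' @return List of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_strains, seed = 1L, n_uogs = 238L,
                                   contig_length = NULL,
                                   intergenic_gap = 200L,
                                   root_state = "LONG", switch_prob = 0.05,
                                   loss_prob = 0, invert_short = TRUE,
                                   divergence = 0.05, target_or = 2.67,
                                   baseline_pathogenic = 0.5,
                                   n_phylogroups = 8L,
                                   founder_clade_short = FALSE,
                                   uog_protein_len = 90L) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  probs <- c(switch_prob = switch_prob, loss_prob = loss_prob,
             divergence = divergence,
             baseline_pathogenic = baseline_pathogenic)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (!is.finite(target_or) || target_or <= 0)
    stop("target_or must be a finite positive number")
  if (!root_state %in% c("LONG", "SHORT"))
    stop("root_state must be LONG or SHORT")
  pp <- .pathotype_probs(target_or, baseline_pathogenic)
  if (any(pp < 0 | pp > 1))
    stop("infeasible pathotype probabilities: P(pathogenic|short) = ",
         signif(pp["short"], 4), ", P(pathogenic|long) = ",
         signif(pp["long"], 4), " must both lie in [0,1]")
  if (n_uogs >= 236) {
    flanks <- c("UOG217", "UOG236")
  } else {
    if (n_uogs < 4) stop("n_uogs must be >= 4")
    mid <- floor(n_uogs / 2)
    flanks <- sprintf("UOG%03d", c(mid, mid + 1L))
  }
  structure(list(n_strains = as.integer(n_strains), seed = as.integer(seed),
                 n_uogs = as.integer(n_uogs), contig_length = contig_length,
                 intergenic_gap = as.integer(intergenic_gap),
                 root_state = root_state, switch_prob = switch_prob,
                 loss_prob = loss_prob, invert_short = invert_short,
                 divergence = divergence, target_or = target_or,
                 baseline_pathogenic = baseline_pathogenic,
                 n_phylogroups = as.integer(n_phylogroups),
                 founder_clade_short = founder_clade_short,
                 uog_protein_len = as.integer(uog_protein_len),
                 flank_uogs = flanks),
            class = "synthetic_panel_config")
}

# symmetric split of the target OR around the baseline odds
.pathotype_probs <- function(target_or, baseline) {
  odds0 <- baseline / (1 - baseline)
  odds_short <- odds0 * sqrt(target_or)
  odds_long <- odds0 / sqrt(target_or)
  c(short = odds_short / (1 + odds_short),
    long = odds_long / (1 + odds_long))
}

#' Simulate a pure-birth strain tree
#'
#' Yule (pure-birth, rate 1) topology with branch lengths, deterministic for
#' a fixed seed; tips are relabeled `strain_001`, `strain_002`, ...
#'
#' @param n Number of tips (>= 2).
#' @param seed RNG seed.
#' @return A `phylo` tree.
#' @export
simulate_tree <- function(n, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  tr$tip.label <- sprintf("strain_%03d", seq_len(n))
  tr
}

# evolve LONG/SHORT/NONE states down the tree
.evolve_states <- function(tree, config) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- rep(NA_character_, ntip + tree$Nnode)
  states[root] <- config$root_state
  ord <- ape::reorder.phylo(tree, "cladewise")
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  founder_child <- -1L
  if (config$founder_clade_short) {
    # flip the larger root-child clade so both states form real clades
    sizes <- vapply(root_children, function(nd) {
      if (nd <= ntip) return(1L)
      length(ape::extract.clade(tree, nd)$tip.label)
    }, integer(1))
    founder_child <- root_children[order(-sizes, root_children)[1]]
  }
  flip <- c(LONG = "SHORT", SHORT = "LONG")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    s <- states[par]
    if (s == "NONE") {
      states[ch] <- "NONE"
      next
    }
    if (config$loss_prob > 0 && runif(1) < config$loss_prob) {
      states[ch] <- "NONE"
      next
    }
    switched <- (ch == founder_child) ||
      (config$switch_prob > 0 && runif(1) < config$switch_prob)
    states[ch] <- if (switched) flip[[s]] else s
  }
  setNames(states[seq_len(ntip)], tree$tip.label)
}

# k deepest clades: repeatedly split the group whose root is closest to the
# tree root until k groups exist
.k_deepest_clades <- function(tree, k) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  kids <- .children_of(tree)
  tips_under <- function(nd) {
    if (nd <= ntip) return(nd)
    unlist(lapply(kids[[as.character(nd)]], tips_under))
  }
  groups <- list(root)
  while (length(groups) < k) {
    internal <- vapply(groups, function(nd) nd > ntip, logical(1))
    if (!any(internal)) break
    cand <- which(internal)
    nd <- groups[[cand[which.min(depth[unlist(groups[cand])])]]]
    i <- which(vapply(groups, identical, logical(1), nd))[1]
    groups <- c(groups[-i], as.list(kids[[as.character(nd)]]))
  }
  labels <- c("A", "B1", "B2", "C", "D", "E", "F", "G",
              sprintf("PG%d", seq_len(max(0, length(groups) - 8)) + 8))
  out <- rep(NA_character_, ntip)
  # deterministic label order: by smallest tip index in the group
  first_tip <- vapply(groups, function(nd) min(tips_under(nd)), numeric(1))
  groups <- groups[order(first_tip)]
  for (i in seq_along(groups))
    out[tips_under(groups[[i]])] <- labels[i]
  setNames(out, tree$tip.label)
}

.mutate_protein <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  aa <- setdiff(AA_ALPHABET, "X")
  hit <- which(runif(length(ch)) < divergence)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate a synthetic strain panel
#'
#' See [synthetic_panel_config()] for the generative model. The panel is
#' fully deterministic for a fixed config (including seed).
#'
#' @param config A `synthetic_panel_config` (or arguments forwarded to it).
#' @return Object of class `strain_panel`: list with `tree`, `genomes`
#'   (named list of `genome_annotation`), `uog_table`, `metadata`
#'   (data.frame strain_id, phylogroup, pathotype), `truth` (data.frame
#'   strain_id, variant, inverted, span_start, span_end, upstream_uog,
#'   downstream_uog), and `config`.
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "synthetic_panel_config"))
    stop("config must be a synthetic_panel_config")
  queries <- yih_query_proteins()
  uog_ref <- uog_reference_proteins(config$n_uogs, config$uog_protein_len)
  fam_order <- yih_families()
  short_fams <- yih_short_families()

  tree <- simulate_tree(config$n_strains, config$seed)
  with_seed(config$seed + 1L, {
    states <- .evolve_states(tree, config)
    phylogroups <- .k_deepest_clades(tree,
                                     min(config$n_phylogroups,
                                         config$n_strains))
    pp <- .pathotype_probs(config$target_or, config$baseline_pathogenic)
    p_path <- ifelse(states == "SHORT", pp["short"],
                     ifelse(states == "LONG", pp["long"],
                            config$baseline_pathogenic))
    pathotype <- ifelse(runif(length(states)) < p_path,
                        "pathogenic", "non-pathogenic")

    # backbone order: numeric UOG order with the second flank moved to
    # immediately follow the first, so the cassette sits strictly between
    uog_ids <- names(uog_ref)
    f1 <- config$flank_uogs[1]; f2 <- config$flank_uogs[2]
    backbone <- c(setdiff(uog_ids[seq_len(match(f1, uog_ids))], f2), f2,
                  setdiff(uog_ids[-seq_len(match(f1, uog_ids))], f2))
    ins_at <- match(f1, backbone) # cassette goes after this slot

    genomes <- list()
    uog_rows <- list()
    truth_rows <- list()
    for (s in tree$tip.label) {
      st <- states[[s]]
      cas_fams <- switch(st, LONG = fam_order, SHORT = short_fams,
                         NONE = character(0))
      cas_strand <- "+"
      if (st == "SHORT" && config$invert_short) {
        cas_fams <- rev(cas_fams)
        cas_strand <- "-"
      }
      ids <- character(0); starts <- integer(0); ends <- integer(0)
      strands <- character(0); prods <- character(0); seqs <- character(0)
      pos <- 1000L
      gi <- 0L
      add_gene <- function(name, prot, strand, product) {
        gi <<- gi + 1L
        glen <- 3L * nchar(prot) + 3L
        ids[gi] <<- sprintf("%s_g%04d", s, gi)
        starts[gi] <<- pos
        ends[gi] <<- pos + glen - 1L
        strands[gi] <<- strand
        prods[gi] <<- product
        seqs[gi] <<- .mutate_protein(prot, config$divergence)
        pos <<- pos + glen + config$intergenic_gap
        ids[gi]
      }
      uog_gene <- character(length(backbone))
      names(uog_gene) <- backbone
      cas_members <- character(0)
      cas_span <- c(NA_integer_, NA_integer_)
      for (b in backbone) {
        uog_gene[b] <- add_gene(b, uog_ref[[b]], "+", b)
        if (b == backbone[ins_at] && length(cas_fams) > 0) {
          first <- TRUE
          for (f in cas_fams) {
            gidx <- add_gene(f, queries[[f]], cas_strand, f)
            cas_members <- c(cas_members, gidx)
            if (first) { cas_span[1] <- starts[gi]; first <- FALSE }
            cas_span[2] <- ends[gi]
          }
        }
      }
      total <- pos - config$intergenic_gap + 999L
      clen <- if (is.null(config$contig_length)) total + 5000L
              else config$contig_length
      if (clen < total) stop("contig_length too small for the gene layout")
      genes <- data.frame(gene_id = ids, contig_id = "chr", start = starts,
                          end = ends, strand = strands, protein_seq = seqs,
                          product = prods, stringsAsFactors = FALSE)
      ctg <- data.frame(contig_id = "chr", length = clen, circular = TRUE,
                        stringsAsFactors = FALSE)
      genomes[[s]] <- genome_annotation(s, ctg, genes)
      uog_rows[[s]] <- data.frame(strain_id = s, gene_id = unname(uog_gene),
                                  uog_id = backbone,
                                  stringsAsFactors = FALSE)
      truth_rows[[s]] <- data.frame(
        strain_id = s, variant = st,
        inverted = if (st == "SHORT") config$invert_short
                   else if (st == "LONG") FALSE else NA,
        span_start = cas_span[1], span_end = cas_span[2],
        upstream_uog = if (st == "NONE") NA_character_ else f1,
        downstream_uog = if (st == "NONE") NA_character_ else f2,
        stringsAsFactors = FALSE)
    }

    metadata <- data.frame(strain_id = tree$tip.label,
                           phylogroup = unname(phylogroups[tree$tip.label]),
                           pathotype = unname(pathotype[tree$tip.label]),
                           stringsAsFactors = FALSE)
    panel <- structure(list(
      tree = tree, genomes = genomes,
      uog_table = uog_table(do.call(rbind, unname(uog_rows))),
      metadata = metadata,
      truth = { t <- do.call(rbind, unname(truth_rows));
                rownames(t) <- NULL; t },
      config = config), class = "strain_panel")
    panel
  })
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf(paste0("<strain_panel> %d strains, %d UOGs, seed %d; ",
                     "variants: %s\n"),
              x$config$n_strains, x$config$n_uogs, x$config$seed,
              paste(names(table(x$truth$variant)), table(x$truth$variant),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Write a strain panel to disk
#'
#' Per strain: `<strain>.gff3` + `<strain>.faa`; shared: `uogs.tsv`,
#' `metadata.tsv`, `tree.nwk`, `truth.json` (schema_version 1, carrying the
#' full config). [read_panel()] reconstructs an equal panel.
#'
#' @param panel A `strain_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
panel_to_disk <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(panel$genomes))
    write_annotation(panel$genomes[[s]],
                     file.path(dir, paste0(s, ".gff3")),
                     file.path(dir, paste0(s, ".faa")))
  write.table(panel$uog_table, file.path(dir, "uogs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(panel$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(panel$tree, file.path(dir, "tree.nwk"))
  cfg <- panel$config
  cfg$contig_length <- cfg$contig_length %||% NA
  jsonlite::write_json(list(schema_version = 1L,
                            config = unclass(cfg),
                            truth = panel$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a strain panel back from disk
#'
#' @param dir Directory written by [panel_to_disk()].
#' @return A `strain_panel`.
#' @export
read_panel <- function(dir) {
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  if (!identical(as.integer(tj$schema_version), 1L))
    stop("unsupported truth.json schema_version: ", tj$schema_version)
  cfg <- tj$config
  if (is.null(cfg$contig_length) || is.na(cfg$contig_length))
    cfg$contig_length <- NULL
  config <- do.call(synthetic_panel_config,
                    cfg[setdiff(names(cfg), "flank_uogs")])
  tree <- read_tree(file.path(dir, "tree.nwk"))
  genomes <- list()
  for (s in tree$tip.label)
    genomes[[s]] <- read_annotation(file.path(dir, paste0(s, ".gff3")),
                                    format = "gff3",
                                    protein_fasta =
                                      file.path(dir, paste0(s, ".faa")),
                                    strain_id = s)
  truth <- as.data.frame(tj$truth, stringsAsFactors = FALSE)
  truth$inverted <- as.logical(truth$inverted)
  structure(list(
    tree = tree, genomes = genomes,
    uog_table = uog_table(read.delim(file.path(dir, "uogs.tsv"),
                                     stringsAsFactors = FALSE)),
    metadata = read.delim(file.path(dir, "metadata.tsv"),
                          stringsAsFactors = FALSE),
    truth = truth, config = config), class = "strain_panel")
}

#' Run the full detection pipeline over a panel
#'
#' Convenience wrapper: [detect_cassettes()] for every genome, returning the
#' list of calls plus the strain-level variant vector.
#'
#' @param panel A `strain_panel` (or named list of `genome_annotation`).
#' @param queries Query family set (defaults to [yih_query_proteins()]).
#' @param uogs UOG table (defaults to the panel's).
#' @param ... Passed to [detect_cassettes()].
#' @return List: `calls` (per strain), `variants` (named vector),
#'   `table` (the cassette table).
#' @export
detect_panel <- function(panel, queries = yih_query_proteins(),
                         uogs = NULL, ...) {
  genomes <- if (inherits(panel, "strain_panel")) panel$genomes else panel
  if (is.null(uogs) && inherits(panel, "strain_panel"))
    uogs <- panel$uog_table
  calls <- lapply(genomes, detect_cassettes, queries = queries,
                  uogs = uogs, ...)
  variants <- vapply(calls, `[[`, character(1), "variant")
  list(calls = calls, variants = variants, table = cassette_table(calls))
}
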