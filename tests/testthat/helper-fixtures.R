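# Shared fixtures, built in code.

# The worked-example chronogram: ((1,2),X) joined with (3,Y), plus outgroup
# 4; X and Y are the only full-genome reference species, so the only node
# carrying a reference dS distribution is MRCA(X,Y) at 80 My.
fig_tree <- function() {
  phy <- ape::read.tree(text =
    "(sp4:100,(((sp1:20,sp2:20):30,spX:50):30,(sp3:60,spY:60):20):20);")
  tips <- phy$tip.label
  host_tree(phy,
            order = stats::setNames(rep("Testorder", length(tips)), tips),
            is_ref = stats::setNames(tips %in% c("spX", "spY"), tips))
}

fig_tree_panel <- function(tree, values = seq(0.1, 1, length.out = 100)) {
  node <- ape::getMRCA(tree$phy, c("spX", "spY"))
  reference_panel(stats::setNames(list(values), node_label(tree, node)), tree)
}

# A small, fast synthetic configuration used across tests.
tiny_config <- function(...) {
  args <- list(n_species = 16, n_orders = 3, n_ref_species = 8,
               tree_age = 100, n_families_per_superfamily = 4,
               n_planted_ht = 2, superfamily_labels = c("Copia", "Mariner"),
               p_vertical_presence = 0.5, panel_size = 200, seed = 7)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Sequence metadata for hand-built alignments.
manual_meta <- function(ids, species, specimen = ids) {
  data.frame(seq_id = ids, specimen = specimen, species = species,
             superfamily = "Copia", family = "f1", stringsAsFactors = FALSE)
}

# Repeat a codon n times as a sequence string.
codon_run <- function(codon, n) paste(rep(codon, n), collapse = "")
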