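# Shared small fixtures, built in code at load time.

# Planted 4-block expression for stage-1 recovery checks.
strongSignalFixture <- function(seed = 1L) {
  makePlantedExpression(plantedDesign(nGenes = 40L, nSamples = 60L,
                                      kBlocks = 4L, withinBlockCorr = 0.9,
                                      seed = seed))
}

# Looser blocks plus overlap genes and noisy annotations: the stage-2
# demonstration fixture. Lower within-block correlation widens the
# box-plot thresholds so a meaningful fraction of genes gets multi-module
# potential lists.
stage2Fixture <- function() {
  sim <- makePlantedExpression(plantedDesign(nGenes = 40L, nSamples = 60L,
                                             kBlocks = 4L,
                                             withinBlockCorr = 0.5,
                                             nOverlapGenes = 6L, seed = 1L))
  toy <- makeToyOntology(sim$labels, termsPerBlock = 3L, noise = 0.2,
                         seed = 1L, geneIds = rownames(sim$expression))
  stage1 <- clusterStage(sim$expression, kMin = 2L, kMax = 8L,
                         config = gaConfig(populationSize = 60L,
                                           generations = 10L),
                         pamMaxIter = 500L, seed = 7L)
  list(sim = sim, toy = toy, stage1 = stage1)
}

# 12-gene 3-block instance whose membership space is small enough to
# enumerate exhaustively.
tinyStage2Fixture <- function() {
  sim <- makePlantedExpression(plantedDesign(nGenes = 12L, nSamples = 40L,
                                             kBlocks = 3L,
                                             withinBlockCorr = 0.6,
                                             seed = 3L))
  toy <- makeToyOntology(sim$labels, termsPerBlock = 2L, noise = 0.2,
                         seed = 3L, geneIds = rownames(sim$expression))
  D <- distanceMatrix(sim$expression)
  pam <- pamRun(D, 3L, maxIter = 500L, seed = 5L)
  partition <- methods::new("ModulePartition", geneIds = rownames(D),
                            medoids = as.integer(pam$medoids),
                            labels = pam$labels, k = 3L,
                            silhouette = meanSilhouette(pam$labels, D))
  list(sim = sim, toy = toy, D = D, partition = partition)
}

# 5-term toy ontology OBO text: root, two children, two grandchildren,
# plus one obsolete stanza and one part_of relationship.
writeToyObo <- function(path) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: child A",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root process",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: child B",
    "namespace: biological_process",
    "is_a: GO:0000001",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: grandchild A1",
    "namespace: biological_process",
    "is_a: GO:0000002",
    "relationship: part_of GO:0000003",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: grandchild B1",
    "namespace: biological_process",
    "is_a: GO:0000003",
    "",
    "[Term]",
    "id: GO:0000006",
    "name: gone",
    "namespace: biological_process",
    "is_a: GO:0000001",
    "is_obsolete: true",
    ""), path)
  path
}
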