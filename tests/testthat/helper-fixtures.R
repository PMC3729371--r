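# Fixtures built in code at test time.

# 3-gene toy GFF3: plus-strand 2-exon coding gene, minus-strand 3-exon
# gene, single-exon gene; includes a UTR feature that readers must ignore
writeToyGFF3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "s1\ttoy\tgene\t1\t500\t.\t+\t.\tID=gA",
    "s1\ttoy\tmRNA\t1\t500\t.\t+\t.\tID=gA.1;Parent=gA",
    "s1\ttoy\texon\t1\t100\t.\t+\t.\tParent=gA.1",
    "s1\ttoy\texon\t201\t500\t.\t+\t.\tParent=gA.1",
    "s1\ttoy\tfive_prime_UTR\t1\t50\t.\t+\t.\tParent=gA.1",
    "s1\ttoy\tCDS\t51\t400\t.\t+\t0\tParent=gA.1",
    "s2\ttoy\tgene\t100\t900\t.\t-\t.\tID=gB",
    "s2\ttoy\tmRNA\t100\t900\t.\t-\t.\tID=gB.1;Parent=gB",
    "s2\ttoy\texon\t100\t200\t.\t-\t.\tParent=gB.1",
    "s2\ttoy\texon\t300\t600\t.\t-\t.\tParent=gB.1",
    "s2\ttoy\texon\t700\t900\t.\t-\t.\tParent=gB.1",
    "s2\ttoy\tCDS\t150\t750\t.\t-\t0\tParent=gB.1",
    "s3\ttoy\tgene\t10\t310\t.\t+\t.\tID=gC",
    "s3\ttoy\tmRNA\t10\t310\t.\t+\t.\tID=gC.1;Parent=gC",
    "s3\ttoy\texon\t10\t310\t.\t+\t.\tParent=gC.1",
    "s3\ttoy\tCDS\t10\t310\t.\t+\t0\tParent=gC.1"), path)
  path
}

writeToyOBO <- function(path = tempfile(fileext = ".obo"),
                        extraLines = character(0)) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: leaf term",
    "namespace: biological_process", "is_a: GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000002", "name: mid term",
    "namespace: biological_process", "is_a: GO:0000003 ! top", "",
    "[Term]", "id: GO:0000003", "name: top term",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000004", "name: part",
    "namespace: cellular_component",
    "relationship: part_of GO:0000003 ! top", "",
    "[Term]", "id: GO:0000005", "name: gone",
    "namespace: biological_process", "is_obsolete: true",
    extraLines), path)
  path
}

writeToyGAF <- function(path = tempfile(fileext = ".gaf"),
                        rows = NULL) {
  gafRow <- function(gene, term, evidence = "IEA", aspect = "P",
                     qualifier = "")
    paste("toy", gene, gene, qualifier, term, "PMID:1", evidence, "",
          aspect, "", "", "protein", "taxon:1", "20130723", "toy", "", "",
          sep = "\t")
  if (is.null(rows))
    rows <- c(gafRow("gene1", "GO:0000001"),
              gafRow("gene1", "GO:0000002", evidence = "ISS"),
              gafRow("gene2", "GO:0000001", aspect = "C"),
              gafRow("gene3", "GO:0000004", aspect = "F", qualifier = "NOT"))
  writeLines(c("!gaf-version: 2.1", rows), path)
  path
}

# minimal ontology object without file round-trip
toyOntology <- function() readOBO(writeToyOBO())
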