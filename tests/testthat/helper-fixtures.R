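# shared in-code fixtures

toy_counts <- function() {
  m <- matrix(c(5, 0, 10,
                7, 3, 0,
                0, 2, 4,
                1, 1, 1,
                0, 0, 6), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("ASV_", 1:5), paste0("S", 1:3)))
  count_matrix(m)
}

toy_taxonomy <- function() {
  data.frame(asv_id = paste0("ASV_", 1:5),
             kingdom = "Fungi", phylum = "", class = "", order = "",
             family = "", genus = "",
             species = c("Aspergillus versicolor", "Wallemia sebi",
                         "Aspergillus versicolor", "", "Botrytis cinerea"),
             stringsAsFactors = FALSE)
}

# a minimal valid reference file; returns its path
write_mini_reference <- function(lines_extra = character()) {
  path <- tempfile(fileext = ".tsv")
  lines <- c("canonical_name\tsynonyms\tminima\termi_group",
             "Aspergillus versicolor\t\t0.74;0.80\t1",
             "Stachybotrys chartarum\tStachybotrys atra\t0.93;0.95\t1",
             "Wallemia sebi\t\t0.69;0.75\tnone",
             "Botrytis cinerea\t\t0.93\t2",
             lines_extra)
  writeLines(lines, path)
  path
}

bundled_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- read_guild_reference(mycodamp_reference())
    db
  }
})

# one default synthetic study shared across test files (generation is the
# expensive step; tests only read it)
default_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- generate_study(scenario_config(), seed = 101)
    st
  }
})
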