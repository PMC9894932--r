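# In-code fixtures: every file is written at test time into tempdirs.

write_toy_sbml <- function(path = tempfile(fileext = ".xml"),
                           with_noid_species = TRUE) {
  noid <- if (with_noid_species) '      <species name="unidentified"/>\n' else ""
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '  <model id="toy">\n',
    '    <listOfSpecies>\n',
    '      <species id="M_glc__D_c" name="D-Glucose"/>\n',
    '      <species id="M_glc__D_e" name="D-Glucose"/>\n',
    '      <species id="M_but_c" name="Butyrate">\n',
    '        <annotation>\n',
    '          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '                   xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
    '            <rdf:Description rdf:about="#M_but_c">\n',
    '              <bqbiol:is>\n',
    '                <rdf:Bag>\n',
    '                  <rdf:li rdf:resource="http://identifiers.org/chebi/CHEBI:17968"/>\n',
    '                  <rdf:li rdf:resource="http://identifiers.org/hmdb/HMDB0000039"/>\n',
    '                </rdf:Bag>\n',
    '              </bqbiol:is>\n',
    '            </rdf:Description>\n',
    '          </rdf:RDF>\n',
    '        </annotation>\n',
    '      </species>\n',
    '      <species id="M_x_e" name="Uptaken nutrient"/>\n',
    noid,
    '    </listOfSpecies>\n',
    '    <listOfReactions>\n',
    '      <reaction id="R_EX_x_e">\n',
    '        <listOfReactants><speciesReference species="M_x_e"/></listOfReactants>\n',
    '      </reaction>\n',
    '      <reaction id="R_conv">\n',
    '        <listOfReactants><speciesReference species="M_glc__D_c"/></listOfReactants>\n',
    '        <listOfProducts><speciesReference species="M_but_c"/></listOfProducts>\n',
    '      </reaction>\n',
    '    </listOfReactions>\n',
    '  </model>\n',
    '</sbml>'), path)
  path
}

write_registry_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  df2 <- df
  df2[] <- lapply(df2, function(x) { x <- as.character(x); x[is.na(x)] <- ""; x })
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

# Small registry pair with known identifier links for cascade tests.
tiny_registry <- function(source_label, rows) {
  microexposome:::new_registry(rows, source_label, "test")
}
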