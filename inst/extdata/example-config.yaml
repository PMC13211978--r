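# Example federation: one relational passport/phenotype source (the
# unprefixed fallback) and two crop-specific genotype sources.
server:
  port: 8080
  tokens: ['${BRAPIFED_TOKEN}']
federation:
  separator: '-'
  missingGenotype: '.'
  onBackendError: fail
backends:
  - name: pheno
    baseUrl: http://pheno.example.org/brapi/v2
    prefix: ''
    endpoints: [commoncropnames, germplasm, samples, studies, observations]
  - name: barley
    baseUrl: http://barley.example.org/brapi/v2
    prefix: bar
    authToken: '${BARLEY_TOKEN}'
    endpoints: [commoncropnames, variants, callsets, allelematrix]
  - name: wheat
    baseUrl: http://wheat.example.org/brapi/v2
    prefix: whe
    authToken: '${WHEAT_TOKEN}'
    endpoints: [commoncropnames, variants, callsets, allelematrix]
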