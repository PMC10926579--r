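{\rtf1\ansi\ansicpg1252\deff0\nouicompat\deflang4105
{\fonttbl{\f0\fnil\fcharset0 Calibri;}{\f1\froman Times New Roman;}}
{\colortbl ;\red0\green0\blue255;}
{\stylesheet{\s0 Normal;}}
{\*\generator Riched20 10.0;}
\viewkind4\uc1
\pard\sa200\sl276\slmult1\f0\fs22\lang9 Specimen: left lung biopsy\par
Interpretation and Comments:\par
The specimen was tested for EGFR mutations.\par
R\'e9sum\'e9 of assay: see below.\par
EGFR Mutation Assay:\par
The deletions in Exon 19 was identified.\par
Note:\par
Assay sensitivity \u8805?5%.\par
Comment:\par
None.\par
}
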