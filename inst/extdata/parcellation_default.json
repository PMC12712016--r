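{
  "version": "macaque-frontoparietal-1.0",
  "areas": [
    {
      "name": "46d",
      "region": "prefrontal",
      "notes": "dorsolateral prefrontal; injected subfields: rostral, intermediate, caudal"
    },
    {
      "name": "46d rostral",
      "region": "prefrontal",
      "notes": "subfield of 46d",
      "parent": "46d"
    },
    {
      "name": "46d intermediate",
      "region": "prefrontal",
      "notes": "subfield of 46d",
      "parent": "46d"
    },
    {
      "name": "46d caudal",
      "region": "prefrontal",
      "notes": "subfield of 46d",
      "parent": "46d"
    },
    {
      "name": "46v",
      "region": "prefrontal",
      "notes": "ventrolateral prefrontal"
    },
    {
      "name": "46v intermediate",
      "region": "prefrontal",
      "notes": "subfield of 46v",
      "parent": "46v"
    },
    {
      "name": "12r",
      "region": "prefrontal",
      "notes": "ventrolateral prefrontal; injected subfields: rostral, intermediate"
    },
    {
      "name": "12r rostral",
      "region": "prefrontal",
      "notes": "subfield of 12r",
      "parent": "12r"
    },
    {
      "name": "12r intermediate",
      "region": "prefrontal",
      "notes": "subfield of 12r",
      "parent": "12r"
    },
    {
      "name": "12l",
      "region": "prefrontal",
      "notes": ""
    },
    {
      "name": "12m",
      "region": "prefrontal",
      "notes": "orbitofrontal"
    },
    {
      "name": "12o",
      "region": "prefrontal",
      "notes": "orbitofrontal"
    },
    {
      "name": "12m/11",
      "region": "prefrontal",
      "notes": "orbitofrontal border zone"
    },
    {
      "name": "45A",
      "region": "prefrontal",
      "notes": ""
    },
    {
      "name": "45B",
      "region": "prefrontal",
      "notes": ""
    },
    {
      "name": "8A-8r",
      "region": "prefrontal",
      "notes": "periarcuate"
    },
    {
      "name": "8B",
      "region": "prefrontal",
      "notes": ""
    },
    {
      "name": "9",
      "region": "prefrontal",
      "notes": "dorsomedial prefrontal"
    },
    {
      "name": "9/8B",
      "region": "prefrontal",
      "notes": "border zone"
    },
    {
      "name": "FEF",
      "region": "prefrontal",
      "notes": "frontal eye fields"
    },
    {
      "name": "10",
      "region": "prefrontal",
      "notes": "frontopolar"
    },
    {
      "name": "11",
      "region": "prefrontal",
      "notes": "orbitofrontal"
    },
    {
      "name": "13",
      "region": "prefrontal",
      "notes": "orbitofrontal"
    },
    {
      "name": "14",
      "region": "prefrontal",
      "notes": "orbitomedial"
    },
    {
      "name": "F1",
      "region": "F1",
      "notes": "primary motor; kept out of the premotor group"
    },
    {
      "name": "F2",
      "region": "premotor",
      "notes": "dorsal premotor"
    },
    {
      "name": "F2d",
      "region": "premotor",
      "notes": "dorsal sector of F2"
    },
    {
      "name": "F3",
      "region": "premotor",
      "notes": "supplementary motor area proper (SMA)"
    },
    {
      "name": "F4",
      "region": "premotor",
      "notes": "ventral premotor"
    },
    {
      "name": "F5",
      "region": "premotor",
      "notes": "ventral premotor"
    },
    {
      "name": "F5a",
      "region": "premotor",
      "notes": "sector of F5"
    },
    {
      "name": "F5p",
      "region": "premotor",
      "notes": "sector of F5"
    },
    {
      "name": "F6",
      "region": "premotor",
      "notes": "pre-supplementary motor area (pre-SMA)"
    },
    {
      "name": "F7",
      "region": "premotor",
      "notes": "rostral dorsal premotor"
    },
    {
      "name": "GrFO",
      "region": "frontal_opercular",
      "notes": "granular frontal opercular"
    },
    {
      "name": "PrCO",
      "region": "frontal_opercular",
      "notes": "precentral opercular"
    },
    {
      "name": "DO",
      "region": "frontal_opercular",
      "notes": "dorsal opercular"
    },
    {
      "name": "PF",
      "region": "parietal",
      "notes": "rostral inferior parietal lobule"
    },
    {
      "name": "PFG",
      "region": "parietal",
      "notes": "inferior parietal lobule"
    },
    {
      "name": "PG",
      "region": "parietal",
      "notes": "inferior parietal lobule"
    },
    {
      "name": "PGm",
      "region": "parietal",
      "notes": "medial parietal"
    },
    {
      "name": "PGop",
      "region": "parietal",
      "notes": "parietal operculum sector"
    },
    {
      "name": "Opt",
      "region": "parietal",
      "notes": "occipito-parieto-temporal"
    },
    {
      "name": "AIP",
      "region": "parietal",
      "notes": "anterior intraparietal"
    },
    {
      "name": "LIP",
      "region": "parietal",
      "notes": "lateral intraparietal"
    },
    {
      "name": "MIP",
      "region": "parietal",
      "notes": "medial intraparietal"
    },
    {
      "name": "VIP",
      "region": "parietal",
      "notes": "ventral intraparietal"
    },
    {
      "name": "PE",
      "region": "parietal",
      "notes": "superior parietal lobule"
    },
    {
      "name": "PEc",
      "region": "parietal",
      "notes": "superior parietal lobule"
    },
    {
      "name": "PEci",
      "region": "parietal",
      "notes": "cingulate sector of PE"
    },
    {
      "name": "PEip",
      "region": "parietal",
      "notes": "intraparietal sector of PE"
    },
    {
      "name": "V6A",
      "region": "parietal",
      "notes": "superior parietal lobule, caudal"
    },
    {
      "name": "ParOp",
      "region": "parietal",
      "notes": "parietal operculum"
    },
    {
      "name": "24",
      "region": "cingulate",
      "notes": "rostral cingulate"
    },
    {
      "name": "24c",
      "region": "cingulate",
      "notes": ""
    },
    {
      "name": "24c/d",
      "region": "cingulate",
      "notes": "cingulate motor sector"
    },
    {
      "name": "23",
      "region": "cingulate",
      "notes": "posterior cingulate"
    },
    {
      "name": "PCC",
      "region": "cingulate",
      "notes": "posterior cingulate cortex"
    },
    {
      "name": "Ins",
      "region": "other",
      "notes": "insula"
    },
    {
      "name": "Ia",
      "region": "other",
      "notes": "agranular insula"
    },
    {
      "name": "Idg",
      "region": "other",
      "notes": "disgranular insula"
    },
    {
      "name": "FST",
      "region": "other",
      "notes": "fundal superior temporal"
    },
    {
      "name": "MST",
      "region": "other",
      "notes": "middle superior temporal"
    },
    {
      "name": "MT",
      "region": "other",
      "notes": "middle temporal"
    },
    {
      "name": "STP",
      "region": "other",
      "notes": "superior temporal polysensory"
    }
  ]
}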