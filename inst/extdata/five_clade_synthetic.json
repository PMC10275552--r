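{
  "island_age": 30,
  "M": 1000,
  "clades": [
    {
      "name": "clade_1",
      "mainland_species_id": 1,
      "status": "endemic_clade",
      "colonization_age": 22.09,
      "branching_ages": [
        21.9112056348054,
        20.8678766834922,
        20.6476385551295,
        20.0623100809846,
        19.8454281409364,
        17.1737649389543,
        17.0057969677681,
        15.8521928475611,
        15.1763346826704,
        14.5970232360344,
        14.395473492837,
        13.8971292297263,
        12.6543307964434,
        10.9941762576625,
        8.5292603042908,
        8.48485113534145,
        8.39497711370466,
        8.22021694297669,
        5.90290457219118,
        5.86508636880899,
        4.68622829513391,
        4.54997835952556,
        4.4551538566174,
        3.90013866336551,
        2.7735120697855,
        1.3648587146285,
        0.295792459479999
      ]
    },
    {
      "name": "clade_2",
      "mainland_species_id": 2,
      "status": "endemic_clade",
      "colonization_age": 13.75,
      "branching_ages": [
        11.9582491286565,
        11.3763831308461,
        11.288011544093,
        10.9207980849897,
        10.85364818573,
        10.7653254814795,
        9.95102550805314,
        9.19141765014501,
        8.89707766502397,
        8.24403009959497,
        7.60424928506836,
        7.28364422771847,
        6.78619297192199,
        6.62860158772673,
        5.65502340759849,
        5.25783440971281,
        4.67979870445561,
        2.56049201940186,
        1.48422485595802,
        0.320804032089654
      ]
    },
    {
      "name": "clade_3",
      "mainland_species_id": 3,
      "status": "endemic_clade",
      "colonization_age": 11.03,
      "branching_ages": [
        8.07742053753231,
        5.26384761735331
      ]
    },
    {
      "name": "clade_4",
      "mainland_species_id": 4,
      "status": "endemic_clade",
      "colonization_age": 8.85,
      "branching_ages": [
        7.62170386996586,
        6.13067427487113,
        4.22693365589948,
        3.87715939893387
      ]
    },
    {
      "name": "clade_5",
      "mainland_species_id": 5,
      "status": "endemic_clade",
      "colonization_age": 8.43,
      "branching_ages": [
        5.58070279420121,
        4.37208683871897,
        3.42957847799873,
        2.66617049155058,
        2.06364104537526,
        0.838499730254989,
        0.595824367431924
      ]
    }
  ]
}
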