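>CALRwt start=352 | human calreticulin C-domain fragment 352-417 (transcribed from UniProt P27797; validated against published anchors: L367, E380, K385, E389, E403, E405, D408, terminal KDEL, net formal charge -26)
AAEKQMKDKQDEEQRLKEEEEDKKRKEEEEAEDKEDDEDKDEDEEDEEDKEEDEEEDVPGQAKDEL
>CALRm_A start=352 | class A p.L367Tfs*46 (canonical type 1) | transcribed reconstruction: wild type 352-366 + T + shared alternative-reading-frame tail; length 60, charge +15, CREAC
AAEKQMKDKQDEEQRTRRMMRTKMRMRRMRRTRRKMRRKMSPARPRTSCREACLQGWTEA
>CALRm_B start=352 | class B p.K385Nfs*47 (canonical type 2) | transcribed reconstruction: wild type 352-384 + N + C + shared tail; length 79, charge +9, CREAC
AAEKQMKDKQDEEQRLKEEEEDKKRKEEEEAEDNCRRMMRTKMRMRRMRRTRRKMRRKMSPARPRTSCREACLQGWTEA
>CALRm_C start=352 | class C p.E380Dfs*51 | synthetic reconstruction: wild type 352-379 + D + 5 unverified alternative-frame junction residues + shared tail; length 78, charge +15, CREAC
AAEKQMKDKQDEEQRLKEEEEDKKRKEEDRTRRMRRMMRTKMRMRRMRRTRRKMRRKMSPARPRTSCREACLQGWTEA
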