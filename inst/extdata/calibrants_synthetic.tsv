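label	neutral_mass_da
C7H12O4	160.0735588632
C9H8O3	164.0473441154
C8H10O4	170.0579087991
C9H12O4	184.0735588632
C11H10O3	190.0629941795
C8H14O5	190.0841235470
C10H14O4	198.0892089274
C9H16O5	204.0997736111
C11H14O5	226.0841235470
C13H12O4	232.0735588632
C10H18O6	234.1103382949
C12H16O5	240.0997736111
C14H14O4	246.0892089274
C11H20O7	264.1209029786
C13H18O6	270.1103382949
C12H22O7	278.1365530427
C14H20O6	284.1259883590
C16H16O5	288.0997736111
C17H16O5	300.0997736111
C15H20O7	312.1209029786
C18H18O5	314.1154236753
C14H24O8	320.1471177265
C16H22O7	326.1365530427
C19H18O6	342.1103382949
C20H20O6	356.1259883590
C17H24O8	356.1471177265
C21H20O6	368.1259883590
C18H24O8	368.1471177265
C16H28O10	380.1682470940
C22H22O7	398.1365530427
C19H26O9	398.1576824102
C23H22O7	410.1365530427
C20H28O9	412.1733324744
C24H24O7	424.1522031069
C18H32O11	424.1944618418
C19H34O11	438.2101119060
C25H24O8	452.1471177265
C22H30O10	454.1838971581
C26H26O8	466.1627677906
C20H36O12	468.2206765897
C27H26O8	478.1627677906
C28H28O8	492.1784178548
C24H34O11	498.2101119060
C21H38O13	498.2312412735
C22H40O13	512.2468913376
C29H28O9	520.1733324744
C30H30O9	534.1889825385
C26H36O12	540.2206765897
C23H40O14	540.2418059572
C27H38O12	554.2363266539
C24H42O14	554.2574560213
C32H32O10	576.1995472222
C28H38O13	582.2312412735
C25H44O15	584.2680207051
C33H32O10	588.1995472222
C34H34O10	602.2151972864
C35H34O10	614.2151972864
C26H46O16	614.2785853888
C30H42O14	626.2574560213
C27H48O16	628.2942354530
C36H36O11	644.2257619701
C32H44O14	652.2731060855
C37H36O11	656.2257619701
C28H50O17	658.3048001367
C38H38O11	670.2414120343
C33H46O15	682.2836707692
C34H48O15	696.2993208334
C39H38O12	698.2363266539
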