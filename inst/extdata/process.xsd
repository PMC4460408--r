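<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <!-- Normative schema for Process documents: header, description, file
       listings (inputs/references/outputs) and the ordered tool steps. -->

  <xs:simpleType name="tokenNoWildcard">
    <xs:restriction base="xs:string">
      <xs:pattern value="[^\{\}\*\s]+"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="quantityType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="single"/>
      <xs:enumeration value="collection"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="fileType">
    <xs:sequence>
      <xs:element name="comment" type="xs:string" minOccurs="0"/>
    </xs:sequence>
    <xs:attribute name="id" type="tokenNoWildcard" use="required"/>
    <xs:attribute name="format" type="xs:string" use="required"/>
    <xs:attribute name="quantity" type="quantityType" use="required"/>
  </xs:complexType>

  <xs:complexType name="fileListType">
    <xs:sequence>
      <xs:element name="file" type="fileType" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="nonEmptyFileListType">
    <xs:sequence>
      <xs:element name="file" type="fileType" minOccurs="1" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="switchType">
    <xs:attribute name="name" type="tokenNoWildcard" use="required"/>
    <xs:attribute name="true" type="xs:string" use="required"/>
    <xs:attribute name="false" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="stepType">
    <xs:sequence>
      <xs:element name="tool" type="xs:string"/>
      <xs:element name="version" type="xs:string"/>
      <xs:element name="command" type="xs:string"/>
      <xs:element name="loop" type="xs:string" minOccurs="0"/>
      <xs:element name="switch" type="switchType" minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="comment" type="xs:string" minOccurs="0"/>
    </xs:sequence>
    <xs:attribute name="index" type="xs:positiveInteger" use="required"/>
  </xs:complexType>

  <xs:element name="process">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="header">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="author" type="xs:string"/>
              <xs:element name="contact" type="xs:string"/>
              <xs:element name="date" type="xs:date"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="description" type="xs:string"/>
        <xs:element name="inputs" type="nonEmptyFileListType"/>
        <xs:element name="references" type="fileListType" minOccurs="0"/>
        <xs:element name="outputs" type="nonEmptyFileListType"/>
        <xs:element name="steps">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="step" type="stepType" minOccurs="1" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="id" type="tokenNoWildcard" use="required"/>
      <xs:attribute name="version" type="xs:positiveInteger" use="required"/>
    </xs:complexType>
    <xs:key name="uniqueFileIdentifier">
      <xs:selector xpath=".//file"/>
      <xs:field xpath="@id"/>
    </xs:key>
  </xs:element>

</xs:schema>
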